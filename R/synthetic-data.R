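#' @importFrom stats setNames
NULL

# Locus architecture templates. Order and strand follow the observed
# bifidobacterial layouts: the Tad (T4cP) cluster is tadZ-tadA-tadB-tadC
# followed in tandem by flp-tadE-tadF, with the prepilin peptidase tadV
# encoded outside the cluster; the T4aP locus carries pilB and pilT on one
# strand and the remaining nine genes on the opposite strand, starting with
# the prepilin pilE/pilA.
.locus_templates <- function() {
  list(
    T4cP_canonical = list(
      system = "T4cP",
      family = c("tadZ", "tadA", "tadB", "tadC", "flp", "tadE", "tadF"),
      strand = rep("+", 7),
      distal_tadV = TRUE,
      edits = character(0)),
    T4cP_deltaC_inverted = list(
      system = "T4cP",
      family = c("tadZ", "tadA", "tadB", "tadF", "tadE", "flp"),
      strand = c("+", "+", "+", "-", "-", "-"),
      distal_tadV = TRUE,
      edits = c("delete:tadC", "invert:prepilin_cluster")),
    T4cP_deltaV = list(
      system = "T4cP",
      family = c("tadZ", "tadA", "tadB", "tadC", "flp", "tadE", "tadF"),
      strand = rep("+", 7),
      distal_tadV = FALSE,
      edits = c("delete:tadV")),
    T4aP_functional = list(
      system = "T4aP",
      family = c("pilB", "pilT", "pilE", "pilV", "pilW", "pilX",
                 "pilC", "pilD", "pilM", "pilN", "pilO"),
      strand = c("+", "+", rep("-", 9)),
      distal_tadV = FALSE,
      edits = character(0)),
    T4aP_nonfunctional = list(
      system = "T4aP",
      family = c("pilB", "pilT", "pilE", "pilV", "pilW", "pilX",
                 "pilC", "pilD", "pilM", "pilN", "pilO"),
      strand = c("+", "+", rep("-", 9)),
      distal_tadV = FALSE,
      edits = c("frameshift:pilC"))
  )
}

#' Names of the available locus templates
#' @return character vector of template names accepted by
#'   \code{\link{simulationConfig}}.
#' @export
locusTemplateNames <- function() names(.locus_templates())

.FAMILY_LENGTHS <- c(
  tadZ = 380L, tadA = 420L, tadB = 300L, tadC = 290L, flp = 80L,
  tadE = 160L, tadF = 170L, tadV = 190L,
  pilT = 350L, pilB = 470L, pilV = 130L, pilW = 140L, pilE = 150L,
  pilC = 400L, pilX = 135L, pilD = 250L, pilM = 340L, pilN = 210L,
  pilO = 220L)

.random_protein <- function(len, aa_freqs = defaultAAFreqs()) {
  paste0("M", paste(sample(names(aa_freqs), len - 1L, replace = TRUE,
                           prob = aa_freqs), collapse = ""))
}

# Back-translate a protein with a within-family codon table; appends TAA.
.back_translate <- function(prot, cond_table) {
  info <- .codon_info()
  aa <- strsplit(prot, "", fixed = TRUE)[[1]]
  codons <- character(length(aa))
  for (a in unique(aa)) {
    cs <- info$families[[a]]
    idx <- which(aa == a)
    if (length(cs) == 1L) codons[idx] <- cs
    else codons[idx] <- sample(cs, length(idx), replace = TRUE,
                               prob = cond_table[cs])
  }
  paste0(paste(codons, collapse = ""), "TAA")
}

# Substitute residues (positions 2..L, keeping the start Met) uniformly among
# the other 19 amino acids. The number of substitutions is fixed at
# round((1 - identity) * L) so the realized identity tracks the target to
# within 1/L instead of fluctuating binomially.
.mutate_protein <- function(prot, identity) {
  aa <- strsplit(prot, "", fixed = TRUE)[[1]]
  L <- length(aa)
  if (L < 2L || identity >= 1) return(prot)
  n_sub <- min(round((1 - identity) * L), L - 1L)
  hit <- sample(2:L, n_sub)
  AA20 <- names(defaultAAFreqs())
  for (i in hit) {
    aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  }
  paste(aa, collapse = "")
}

# Draw a gene codon-by-codon from a joint codon distribution; start codon
# forced to ATG, stop TAA appended.
.gene_from_joint <- function(len_codons, joint) {
  codons <- sample(names(joint), len_codons, replace = TRUE, prob = joint)
  codons[1L] <- "ATG"
  paste0(paste(codons, collapse = ""), "TAA")
}

# Delete one nucleotide near the middle of the CDS: length is no longer a
# multiple of 3, downstream codons go out of frame.
.frameshift_cds <- function(cds) {
  n <- nchar(cds)
  pos <- max(4L, 3L * (n %/% 6L) + 1L)
  paste0(substr(cds, 1L, pos - 1L), substr(cds, pos + 1L, n))
}

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# within-family conditional table implied by a joint distribution
.cond_from_joint <- function(joint) {
  info <- .codon_info()
  out <- joint
  for (a in names(info$families)) {
    cs <- info$families[[a]]
    out[cs] <- joint[cs] / sum(joint[cs])
  }
  out
}

#' Generate the reference T4P protein family set
#'
#' Builds one synthetic reference protein (and its back-translated CDS) for
#' each of the 19 pilus gene families: the 8 tight-adherence (T4cP) families
#' tadZ, tadA, tadB, tadC, flp, tadE, tadF, tadV and the 11 type IVa (T4aP)
#' families pilT, pilB, pilV, pilW, pilE (pilE/pilA treated as one family),
#' pilC, pilX, pilD, pilM, pilN, pilO. Proteins are 80-500 aa and mutually
#' dissimilar (every pairwise global identity < 0.30, verified with the
#' package aligner and regenerated on violation). Deterministic for a given
#' seed; the caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @return list with elements \code{proteins} (\code{AAStringSet}),
#'   \code{cds} (\code{DNAStringSet}), \code{system} (named character,
#'   \code{"T4cP"}/\code{"T4aP"} per family).
#' @examples
#' fams <- makeReferenceFamilies(seed = 1)
#' length(fams$proteins)  # 19
#' @export
makeReferenceFamilies <- function(seed = 42L) {
  key <- paste0("fams_", seed)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  lens <- .FAMILY_LENGTHS
  prots <- vapply(lens, .random_protein, character(1))
  # enforce mutual dissimilarity; random proteins essentially always pass
  for (round in 1:50) {
    ok <- TRUE
    nm <- names(prots)
    for (i in seq_along(prots)[-length(prots)]) {
      for (j in (i + 1L):length(prots)) {
        id <- pairwiseIdentity(prots[[i]], prots[[j]])["identity"]
        if (id >= 0.30) {
          prots[[j]] <- .random_protein(lens[[j]])
          ok <- FALSE
        }
      }
    }
    if (ok) break
  }
  if (!ok) stop("could not generate mutually dissimilar reference families")
  tab <- defaultCodonTable()
  cds <- vapply(prots, .back_translate, character(1), cond_table = tab)
  system <- setNames(ifelse(grepl("^pil", names(lens)), "T4aP", "T4cP"),
                     names(lens))
  res <- list(proteins = AAStringSet(prots), cds = DNAStringSet(cds),
              system = system)
  .pkg_cache[[key]] <- res
  res
}

#' Build and validate a simulation configuration
#'
#' Assembles the configuration for \code{\link{simulateGenomes}}. Defaults
#' describe the study conditions the downstream stages are validated under:
#' GC-biased background codon usage, a small minority of compositionally
#' alien genes shifted +0.15 in GC and flattened in codon usage, one embedded
#' canonical Tad locus per genome at 0.8 protein identity to the references,
#' and 70\% of genomes sharing the conserved locus-flanking gene pair.
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param n_genomes number of genomes to emit.
#' @param n_background_genes background genes per genome (minimum 30).
#' @param gene_length_codons integer range (length 2) of background gene
#'   lengths in amino-acid codons.
#' @param background_codon_table within-family codon probabilities (each
#'   synonymous family sums to 1).
#' @param aa_freqs background amino-acid frequencies.
#' @param n_alien_genes compositionally alien genes planted per genome.
#' @param alien_gc_shift GC increase of the alien codon distribution.
#' @param alien_flatten uniform-mixture weight of the alien distribution.
#' @param loci_to_embed list of \code{list(template=, target_identity=)};
#'   template one of \code{\link{locusTemplateNames}}; every genome receives
#'   every listed locus.
#' @param flank_conservation fraction of genomes receiving the conserved
#'   (orthologous) upstream/downstream flanking pair around the first
#'   embedded locus; the rest keep genome-private neighbours.
#' @param shared_background_fraction fraction of background genes drawn from
#'   a shared ancestral gene set (mutated per genome), so that a single-copy
#'   core exists for pangenome and phylogeny stages.
#' @param shared_background_identity per-genome protein identity to the
#'   shared ancestral genes.
#' @param alien_usage_rates named numeric vector: for each named locus family,
#'   the fraction of genomes in which that family's embedded gene is emitted
#'   with the alien codon distribution (emulating horizontally acquired locus
#'   genes such as pilX/pilE).
#' @param scattered_pilE list(per_genome=, alien_rate=): pilE copies placed
#'   outside any locus in every genome, and the fraction of genomes in which
#'   those copies use the alien codon distribution.
#' @param intergenic_nt fixed intergenic spacer length (random sequence).
#' @param families_seed seed for \code{\link{makeReferenceFamilies}}.
#' @return validated configuration (class \code{piliscan_sim_config}).
#' @export
simulationConfig <- function(seed = 1L,
                             n_genomes = 5L,
                             n_background_genes = 200L,
                             gene_length_codons = c(100L, 400L),
                             background_codon_table = defaultCodonTable(),
                             aa_freqs = defaultAAFreqs(),
                             n_alien_genes = 5L,
                             alien_gc_shift = 0.15,
                             alien_flatten = 0.5,
                             loci_to_embed = list(
                               list(template = "T4cP_canonical",
                                    target_identity = 0.8)),
                             flank_conservation = 0.7,
                             shared_background_fraction = 0.3,
                             shared_background_identity = 0.95,
                             alien_usage_rates = numeric(0),
                             scattered_pilE = list(per_genome = 0L,
                                                   alien_rate = 0),
                             intergenic_nt = 50L,
                             families_seed = 42L) {
  info <- .codon_info()
  for (a in names(info$families)) {
    s <- sum(background_codon_table[info$families[[a]]])
    if (abs(s - 1) > 1e-6)
      stop("config error: background_codon_table family '", a,
           "' does not sum to 1")
  }
  if (n_background_genes < 30L)
    stop("config error: n_background_genes must be >= 30")
  if (length(gene_length_codons) != 2L ||
      gene_length_codons[1] < 30L ||
      gene_length_codons[2] < gene_length_codons[1])
    stop("config error: gene_length_codons must be an increasing range >= 30")
  for (sp in loci_to_embed) {
    if (!sp$template %in% locusTemplateNames())
      stop("config error: unknown locus template '", sp$template, "'")
    if (sp$target_identity <= 0 || sp$target_identity > 1)
      stop("config error: target_identity must be in (0, 1]")
  }
  if (flank_conservation < 0 || flank_conservation > 1)
    stop("config error: flank_conservation must be in [0, 1]")
  if (length(alien_usage_rates) &&
      (is.null(names(alien_usage_rates)) ||
       !all(names(alien_usage_rates) %in% names(.FAMILY_LENGTHS))))
    stop("config error: alien_usage_rates must be named by locus families")
  # fails early when the GC shift is unattainable
  alienCodonTable(background_codon_table, aa_freqs, alien_gc_shift,
                  alien_flatten)
  cfg <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
              n_background_genes = as.integer(n_background_genes),
              gene_length_codons = as.integer(gene_length_codons),
              background_codon_table = background_codon_table,
              aa_freqs = aa_freqs,
              n_alien_genes = as.integer(n_alien_genes),
              alien_gc_shift = alien_gc_shift,
              alien_flatten = alien_flatten,
              loci_to_embed = loci_to_embed,
              flank_conservation = flank_conservation,
              shared_background_fraction = shared_background_fraction,
              shared_background_identity = shared_background_identity,
              alien_usage_rates = alien_usage_rates,
              scattered_pilE = scattered_pilE,
              intergenic_nt = as.integer(intergenic_nt),
              families_seed = as.integer(families_seed))
  class(cfg) <- "piliscan_sim_config"
  cfg
}

# one emitted gene: list(id=, cds=, strand=, role=, family=, extra...)
.unit <- function(cds, strand, role, family = NA_character_) {
  list(cds = cds, strand = strand, role = role, family = family)
}

#' Simulate annotated genomes with ground truth
#'
#' Emits \code{n_genomes} single-contig annotated genomes exhibiting the
#' structure every downstream stage assumes: biased background codon usage; a
#' minority of alien genes drawn from a GC-shifted, flattened codon
#' distribution; T4cP/T4aP locus templates embedded as contiguous gene runs in
#' template order and strand layout, each member mutated to the target protein
#' identity and back-translated with the genome's own codon table (so embedded
#' loci do not look alien to the HGT screen unless explicitly planted via
#' \code{alien_usage_rates}); template edits (tadC deletion plus prepilin
#' sub-cluster inversion, tadV deletion, pilC frameshift); a distal tadV
#' placed at least 10 genes away from the canonical cluster; and conserved
#' versus genome-private locus-flanking genes at the configured fraction.
#'
#' Deterministic: identical config (including seed) gives identical output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{genomes} (named list of
#'   \code{\linkS4class{Genome}}), \code{manifest} (ground truth; see below)
#'   and \code{families} (the reference set used). The manifest holds, per
#'   genome: alien gene ids, embedded locus extents with per-gene family
#'   labels and applied edits, the distal tadV id, flank group and flank gene
#'   ids, scattered pilE ids, and all alien-usage gene ids.
#' @export
simulateGenomes <- function(config) {
  stopifnot(inherits(config, "piliscan_sim_config"))
  fams <- makeReferenceFamilies(config$families_seed)
  set.seed(config$seed)
  info <- .codon_info()
  bg_joint <- .joint_codon_dist(config$background_codon_table,
                                config$aa_freqs)
  alien_joint <- alienCodonTable(config$background_codon_table,
                                 config$aa_freqs, config$alien_gc_shift,
                                 config$alien_flatten)
  # alien-usage planting keeps the protein, so the only signal available is
  # synonymous choice: uniform within-family usage maximizes the RSCU/ENC/CAI
  # departure from the biased host background
  alien_cond <- config$background_codon_table
  for (a in names(info$families)) {
    cs <- info$families[[a]]
    alien_cond[cs] <- 1 / length(cs)
  }
  n <- config$n_genomes
  lo <- config$gene_length_codons[1]; hi <- config$gene_length_codons[2]

  n_shared <- round(config$shared_background_fraction *
                    config$n_background_genes)
  shared_lens <- if (n_shared > 0) sample(lo:hi, n_shared, replace = TRUE)
                 else integer(0)
  shared_prots <- vapply(shared_lens, .random_protein, character(1),
                         aa_freqs = config$aa_freqs)
  flank_prots <- c(up = .random_protein(250L, config$aa_freqs),
                   down = .random_protein(250L, config$aa_freqs))
  conserved_set <- sort(sample.int(n, round(config$flank_conservation * n)))
  alien_usage_sets <- lapply(config$alien_usage_rates, function(r)
    sort(sample.int(n, round(r * n))))
  scat_cfg <- config$scattered_pilE
  scat_alien_set <- if (scat_cfg$per_genome > 0)
    sort(sample.int(n, round(scat_cfg$alien_rate * n))) else integer(0)

  genomes <- list()
  manifest <- list(genomes = list(),
                   conserved_flank_genomes = conserved_set,
                   alien_usage_genomes = alien_usage_sets,
                   scattered_alien_genomes = scat_alien_set)
  templates <- .locus_templates()

  for (g in seq_len(n)) {
    gid <- sprintf("sg%02d", g)
    units <- list()
    role_tags <- character(0)

    # background: shared (ancestral, mutated) + private (codon-by-codon)
    for (s in seq_len(n_shared)) {
      p <- .mutate_protein(shared_prots[s], config$shared_background_identity)
      units[[length(units) + 1L]] <-
        .unit(.back_translate(p, config$background_codon_table),
              sample(c("+", "-"), 1), sprintf("shared_bg_%03d", s))
    }
    n_priv <- config$n_background_genes - n_shared
    for (s in seq_len(n_priv)) {
      len <- sample(lo:hi, 1L)
      units[[length(units) + 1L]] <-
        .unit(.gene_from_joint(len, bg_joint), sample(c("+", "-"), 1),
              "private_bg")
    }
    units <- units[sample.int(length(units))]
    # alien genes interleaved at random positions
    for (s in seq_len(config$n_alien_genes)) {
      len <- sample(lo:hi, 1L)
      au <- .unit(.gene_from_joint(len, alien_joint), sample(c("+", "-"), 1),
                  "alien")
      pos <- sample.int(length(units) + 1L, 1L)
      units <- append(units, list(au), after = pos - 1L)
    }

    # locus blocks
    B <- length(units)
    locus_blocks <- list()
    for (li in seq_along(config$loci_to_embed)) {
      sp <- config$loci_to_embed[[li]]
      tpl <- templates[[sp$template]]
      block <- list()
      alien_fams_here <- names(alien_usage_sets)[vapply(
        names(alien_usage_sets), function(f) g %in% alien_usage_sets[[f]],
        logical(1))]
      for (k in seq_along(tpl$family)) {
        fam <- tpl$family[k]
        p <- .mutate_protein(as.character(fams$proteins[[fam]]),
                             sp$target_identity)
        tab <- if (fam %in% alien_fams_here) alien_cond
               else config$background_codon_table
        cds <- .back_translate(p, tab)
        if (paste0("frameshift:", fam) %in% tpl$edits)
          cds <- .frameshift_cds(cds)
        u <- .unit(cds, tpl$strand[k], paste0("locus", li), fam)
        u$alien_usage <- fam %in% alien_fams_here
        block[[k]] <- u
      }
      tadv_unit <- NULL
      if (tpl$distal_tadV) {
        p <- .mutate_protein(as.character(fams$proteins[["tadV"]]),
                             sp$target_identity)
        tadv_unit <- .unit(.back_translate(p,
                                           config$background_codon_table),
                           "+", paste0("locus", li, "_tadV"), "tadV")
      }
      locus_blocks[[li]] <- list(spec = sp, tpl = tpl, block = block,
                                 tadv = tadv_unit)
    }

    # insertion positions spread along the background
    nl <- length(locus_blocks)
    ins_at <- round(B * (0.22 + 0.40 * (seq_len(nl) - 1L))) +
      sample(0:2, nl, replace = TRUE)
    offset <- 0L
    flank_ids_pending <- NULL
    for (li in seq_along(locus_blocks)) {
      lb <- locus_blocks[[li]]
      pieces <- lb$block
      if (li == 1L && g %in% conserved_set) {
        up <- .unit(.back_translate(
          .mutate_protein(flank_prots["up"], 0.95),
          config$background_codon_table), "+", "flank_up")
        dn <- .unit(.back_translate(
          .mutate_protein(flank_prots["down"], 0.95),
          config$background_codon_table), "+", "flank_down")
        pieces <- c(list(up), pieces, list(dn))
      }
      pos <- min(ins_at[li] + offset, length(units) - 15L)
      units <- append(units, pieces, after = pos)
      if (!is.null(lb$tadv)) {
        # >= 10 intervening genes between cluster end and tadV
        tv_pos <- pos + length(pieces) + 10L + sample(0:3, 1L)
        tv_pos <- min(tv_pos, length(units))
        units <- append(units, list(lb$tadv), after = tv_pos)
      }
      offset <- offset + length(pieces) + !is.null(lb$tadv)
    }

    # scattered pilE copies near the start of the contig, far from any locus
    for (s in seq_len(scat_cfg$per_genome)) {
      p <- .mutate_protein(as.character(fams$proteins[["pilE"]]), 0.8)
      tab <- if (g %in% scat_alien_set) alien_cond
             else config$background_codon_table
      su <- .unit(.back_translate(p, tab), sample(c("+", "-"), 1),
                  "scattered_pilE", "pilE")
      su$alien_usage <- g %in% scat_alien_set
      units <- append(units, list(su), after = min(2L + s, length(units)))
    }

    # emit contig
    ids <- sprintf("%s_g%04d", gid, seq_along(units))
    spac <- config$intergenic_nt
    seqs <- character(length(units))
    starts <- integer(length(units)); ends <- integer(length(units))
    pos <- 0L
    pieces <- character(0)
    for (k in seq_along(units)) {
      sp_nt <- .random_nt(spac)
      cds <- units[[k]]$cds
      placed <- if (units[[k]]$strand == "-")
        as.character(reverseComplement(DNAString(cds))) else cds
      pieces <- c(pieces, sp_nt, placed)
      starts[k] <- pos + spac + 1L
      ends[k] <- starts[k] + nchar(cds) - 1L
      pos <- ends[k]
    }
    pieces <- c(pieces, .random_nt(spac))
    contig <- DNAStringSet(paste(pieces, collapse = ""))
    names(contig) <- paste0(gid, "_c1")
    gr <- GRanges(seqnames = names(contig),
                  ranges = IRanges(starts, ends),
                  strand = vapply(units, `[[`, character(1), "strand"),
                  gene_id = ids)
    genomes[[gid]] <- newGenome(gid, contig, gr)

    roles <- vapply(units, `[[`, character(1), "role")
    fams_u <- vapply(units, `[[`, character(1), "family")
    alien_use <- vapply(units, function(u)
      isTRUE(u$alien_usage), logical(1))
    loci_manifest <- list()
    for (li in seq_along(locus_blocks)) {
      in_block <- roles == paste0("locus", li)
      tv <- roles == paste0("locus", li, "_tadV")
      loci_manifest[[li]] <- list(
        template = locus_blocks[[li]]$spec$template,
        system = locus_blocks[[li]]$tpl$system,
        target_identity = locus_blocks[[li]]$spec$target_identity,
        genes = setNames(as.list(fams_u[in_block]), ids[in_block]),
        distal_tadV = if (any(tv)) ids[tv] else NULL,
        edits = locus_blocks[[li]]$tpl$edits,
        alien_usage_genes = ids[in_block & alien_use])
    }
    manifest$genomes[[gid]] <- list(
      alien_genes = ids[roles == "alien"],
      loci = loci_manifest,
      flank_group = if (g %in% conserved_set) "conserved" else "private",
      flank_genes = if (g %in% conserved_set)
        c(up = ids[roles == "flank_up"], down = ids[roles == "flank_down"])
        else NULL,
      scattered_pilE = ids[roles == "scattered_pilE"],
      alien_usage_genes = ids[alien_use])
  }
  list(genomes = genomes, manifest = manifest, families = fams)
}

#' Write a simulation to disk
#'
#' Writes FASTA + GFF3 per genome plus \code{truth_manifest.json} and the
#' reference family proteins (\code{families.faa}).
#'
#' @param sim result of \code{\link{simulateGenomes}}.
#' @param out_dir output directory.
#' @return invisibly, the output directory.
#' @export
writeSimulation <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (g in sim$genomes) writeGenome(g, out_dir)
  Biostrings::writeXStringSet(sim$families$proteins,
                              file.path(out_dir, "families.faa"))
  jsonlite::write_json(sim$manifest,
                       file.path(out_dir, "truth_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
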