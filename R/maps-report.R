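.family_palette <- function(families) {
  families <- sort(unique(families))
  cols <- grDevices::hcl.colors(max(length(families), 3L), palette = "Dark 3")
  setNames(cols[seq_along(families)], families)
}

#' Render genetic maps of detected loci as SVG
#'
#' One row per locus. Each gene is drawn as an arrow whose horizontal extent
#' is proportional to the ORF length, pointing by strand and filled by family.
#' Percent-identity labels against the corresponding gene of the reference
#' locus are placed between the rows. Output is deterministic for fixed input.
#'
#' @param loci list of \code{\linkS4class{LocusModel}}, all of one system.
#' @param genomes named list of \code{\linkS4class{Genome}} supplying the
#'   member proteins for the identity labels.
#' @param reference index of the reference locus (default 1; its row carries
#'   no labels).
#' @param nt_per_px scale: nucleotides per pixel (> 0).
#' @param colors optional named family -> fill color map.
#' @param out_file optional path; when given the SVG is also written there.
#' @return SVG document as a single character string.
#' @export
renderMap <- function(loci, genomes, reference = 1L, nt_per_px = 10,
                      colors = NULL, out_file = NULL) {
  if (length(loci) == 0L) stop("empty loci list")
  systems <- vapply(loci, function(l) l@system, character(1))
  if (length(unique(systems)) != 1L)
    stop("all loci in one map must belong to the same system")
  stopifnot(nt_per_px > 0)
  mem_all <- lapply(loci, function(l) as.data.frame(members(l)))
  if (is.null(colors))
    colors <- .family_palette(unlist(lapply(mem_all, `[[`, "family")))
  prot_of <- function(gid, gene) {
    g <- genomes[[which(vapply(genomes, genomeId, character(1)) == gid)[1]]]
    as.character(proteinSeqs(g)[[gene]])
  }
  ref_mem <- mem_all[[reference]]
  margin <- 30; row_h <- 70; body_h <- 14; head_w <- 8
  rows_svg <- character(0)
  max_x <- 0
  for (k in seq_along(loci)) {
    m <- mem_all[[k]]
    m <- m[!m$distal, , drop = FALSE]
    x0 <- min(m$start)
    y <- margin + (k - 1) * row_h + row_h / 2
    rows_svg <- c(rows_svg, sprintf(
      '<text class="locus-label" x="%d" y="%.1f" font-size="11">%s (%s)</text>',
      5L, y - body_h, loci[[k]]@locusId, loci[[k]]@classification))
    for (i in seq_len(nrow(m))) {
      x1 <- margin + (m$start[i] - x0) / nt_per_px
      len_px <- (m$end[i] - m$start[i] + 1) / nt_per_px
      x2 <- x1 + len_px
      max_x <- max(max_x, x2)
      hw <- min(head_w, len_px)
      pts <- if (m$strand[i] == "+") {
        sprintf("%.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f",
                x1, y - body_h / 2, x2 - hw, y - body_h / 2, x2, y,
                x2 - hw, y + body_h / 2, x1, y + body_h / 2)
      } else {
        sprintf("%.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f",
                x2, y - body_h / 2, x1 + hw, y - body_h / 2, x1, y,
                x1 + hw, y + body_h / 2, x2, y + body_h / 2)
      }
      rows_svg <- c(rows_svg, sprintf(
        paste0('<polygon class="gene-arrow" data-family="%s" ',
               'data-length-px="%.1f" points="%s" fill="%s" stroke="black" ',
               'stroke-width="0.5"/>'),
        m$family[i], len_px, pts, colors[[m$family[i]]]))
      rows_svg <- c(rows_svg, sprintf(
        '<text class="gene-label" x="%.1f" y="%.1f" font-size="9" text-anchor="middle">%s</text>',
        (x1 + x2) / 2, y - body_h / 2 - 3, m$family[i]))
      if (k != reference) {
        j <- which(ref_mem$family == m$family[i])[1]
        if (!is.na(j)) {
          pid <- pairwiseIdentity(
            prot_of(loci[[k]]@genomeId, m$gene_id[i]),
            prot_of(loci[[reference]]@genomeId, ref_mem$gene_id[j]))
          rows_svg <- c(rows_svg, sprintf(
            '<text class="identity-label" x="%.1f" y="%.1f" font-size="9" text-anchor="middle">%s</text>',
            (x1 + x2) / 2, y + body_h / 2 + 12,
            sprintf("%.0f", 100 * pid[["identity"]])))
        }
      }
    }
  }
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
    max_x + margin, margin * 2 + row_h * length(loci)),
    rows_svg, "</svg>")
  doc <- paste(svg, collapse = "\n")
  if (!is.null(out_file)) writeLines(doc, out_file)
  invisible(doc)
}

.cfg_get <- function(cfg, path, default = NULL, required = FALSE) {
  x <- cfg
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(x[[p]])) {
      if (required)
        stop("config error: required field '", path, "' is missing")
      return(default)
    }
    x <- x[[p]]
  }
  x
}

#' Run the full pipeline
#'
#' Orchestrates simulate (optional) -> genome IO -> codon metrics -> HGT
#' screen -> locus scan -> ortholog clustering -> core tree -> locus
#' neighborhood -> genetic maps, writing all consolidated reports plus a run
#' manifest (package version, seed, parameters). Outputs are a pure function
#' of (inputs, config): rerunning with the same seed reproduces every file
#' byte for byte. Per-stage timings go to the message stream.
#'
#' @param config path to a YAML configuration or an equivalent named list.
#'   Either a \code{simulate:} block (fields of \code{\link{simulationConfig}})
#'   or an \code{input:} block (\code{genome_dir} with FASTA+GFF3 pairs and
#'   \code{families}, a protein FASTA of the 19 reference families) must be
#'   present; a \code{thresholds:} block may override \code{min_id},
#'   \code{min_cov}, \code{max_gap_genes}, \code{min_flags},
#'   \code{ortholog_min_identity} and \code{mcl_inflation}; optional
#'   \code{outgroup}.
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- .cfg_get(cfg, "seed", default = 1L)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[piliscan] %-14s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  tsv <- function(df, file)
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    sim_cfg <- simulationConfig(
      seed = seed,
      n_genomes = .cfg_get(sc, "n_genomes", 5L),
      n_background_genes = .cfg_get(sc, "n_background_genes", 200L),
      gene_length_codons = unlist(.cfg_get(sc, "gene_length_codons",
                                           c(100L, 400L))),
      n_alien_genes = .cfg_get(sc, "n_alien_genes", 5L),
      alien_gc_shift = .cfg_get(sc, "alien_gc_shift", 0.15),
      loci_to_embed = .cfg_get(sc, "loci_to_embed", list(
        list(template = "T4cP_canonical", target_identity = 0.8))),
      flank_conservation = .cfg_get(sc, "flank_conservation", 0.7),
      alien_usage_rates = unlist(.cfg_get(sc, "alien_usage_rates",
                                          numeric(0))),
      scattered_pilE = .cfg_get(sc, "scattered_pilE",
                                list(per_genome = 0L, alien_rate = 0)))
    sim <- stage("simulate", simulateGenomes(sim_cfg))
    stage("write genomes", writeSimulation(sim, file.path(out_dir, "genomes")))
    genomes <- sim$genomes
    families <- sim$families
  } else if (!is.null(cfg$input)) {
    gdir <- .cfg_get(cfg, "input.genome_dir", required = TRUE)
    fam_path <- .cfg_get(cfg, "input.families", required = TRUE)
    fas <- sort(list.files(gdir, pattern = "\\.(fna|fa|fasta)$",
                           full.names = TRUE))
    genomes <- stage("read genomes", {
      gl <- lapply(fas, function(f) {
        gff <- file.path(gdir, paste0(tools::file_path_sans_ext(basename(f)),
                                      ".gff3"))
        if (!file.exists(gff))
          stop("missing GFF3 companion for ", basename(f))
        readGenome(f, gff)
      })
      setNames(gl, vapply(gl, genomeId, character(1)))
    })
    families <- Biostrings::readAAStringSet(fam_path)
    sim <- NULL
  } else {
    stop("config error: one of 'simulate' or 'input' must be present")
  }

  th <- function(f, d) .cfg_get(cfg, paste0("thresholds.", f), d)
  profiles <- stage("codon metrics", {
    lapply(genomes, profileGenome)
  })
  mt <- do.call(rbind, lapply(names(profiles), function(g)
    cbind(genome_id = g, profiles[[g]])))
  tsv(mt, "metrics.tsv")

  calls <- stage("hgt screen", {
    do.call(rbind, lapply(names(profiles), function(g)
      cbind(genome_id = g,
            compositeCall(percentileFlags(profiles[[g]]),
                          k = th("min_flags", 3L)))))
  })
  tsv(calls, "hgt_calls.tsv")

  scans <- stage("locus scan", {
    lapply(genomes, scanGenome, families = families,
           min_id = th("min_id", 0.4), min_cov = th("min_cov", 0.6),
           max_gap_genes = th("max_gap_genes", 5L))
  })
  asg <- do.call(rbind, lapply(names(scans), function(g) {
    a <- scans[[g]]$assignments
    if (nrow(a)) cbind(genome_id = g, a) else NULL
  }))
  loci <- unlist(lapply(scans, `[[`, "loci"), recursive = FALSE)
  loci_json <- lapply(loci, function(l) list(
    locus_id = l@locusId, genome_id = l@genomeId, system = l@system,
    classification = l@classification, tadV_distal = l@tadVDistal,
    extra_pilE_in_locus = l@extraPilE,
    scattered_prepilins = l@scatteredPrepilins, notes = l@notes,
    members = as.data.frame(members(l))))
  jsonlite::write_json(loci_json, file.path(out_dir, "loci.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  rates <- NULL
  if (!is.null(asg) && nrow(asg)) {
    ft <- asg[, c("genome_id", "gene_id", "family")]
    # scattered prepilins get their own context label
    in_locus <- unlist(lapply(loci, function(l) paste(l@genomeId,
                                                      members(l)$gene_id)))
    scat <- ft$family == "pilE" & !(paste(ft$genome_id, ft$gene_id) %in%
                                    in_locus)
    ft$family[scat] <- "pilE_scattered"
    rates <- acquisitionRates(calls, ft)
    tsv(rates, "acquisition_rates.tsv")
  }

  ocs <- stage("orthologs", {
    o <- clusterOrthologs(genomes,
                          min_identity = th("ortholog_min_identity", 0.8),
                          inflation = th("mcl_inflation", 2.0))
    coreFamilies(o)
  })
  tsv(as.data.frame(clusterTable(ocs)), "clusters.tsv")

  tree <- NULL
  if (length(coreIds(ocs)) > 0L && length(genomes) >= 2L) {
    tree <- stage("core tree", {
      d <- coreDistances(ocs, genomes)
      njTree(d, outgroup = .cfg_get(cfg, "outgroup"))
    })
    writeLines(tree, file.path(out_dir, "tree.nwk"))
  }

  nb <- NULL
  t4cp_present <- any(vapply(loci, function(l) l@system == "T4cP",
                             logical(1)))
  if (t4cp_present) {
    nb <- stage("neighborhood", flankConservation(loci, ocs, genomes,
                                                  system = "T4cP"))
    pr <- nb$pairs
    pr$matches_modal <- pr$upstream == nb$modal_pair[1] &
      pr$downstream == nb$modal_pair[2]
    tsv(pr, "neighborhood.tsv")
  }

  stage("maps", {
    mdir <- file.path(out_dir, "maps")
    if (!dir.exists(mdir)) dir.create(mdir)
    for (sys in c("T4cP", "T4aP")) {
      ls <- Filter(function(l) l@system == sys, loci)
      if (length(ls) > 0L)
        renderMap(ls, genomes,
                  out_file = file.path(mdir, paste0(sys, ".svg")))
    }
    NULL
  })

  manifest <- list(
    package = "piliscan",
    version = as.character(utils::packageVersion("piliscan")),
    seed = seed,
    parameters = list(
      min_id = th("min_id", 0.4), min_cov = th("min_cov", 0.6),
      max_gap_genes = th("max_gap_genes", 5L),
      min_flags = th("min_flags", 3L),
      ortholog_min_identity = th("ortholog_min_identity", 0.8),
      mcl_inflation = th("mcl_inflation", 2.0)),
    n_genomes = length(genomes),
    n_loci = length(loci),
    n_clusters = length(unique(clusterTable(ocs)$cluster_id)),
    n_core = length(coreIds(ocs)),
    flank_conservation = if (!is.null(nb)) nb$conservation else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genomes = genomes, sim = sim, profiles = profiles,
                 calls = calls, scans = scans, loci = loci, rates = rates,
                 ocs = ocs, tree = tree, neighborhood = nb))
}
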