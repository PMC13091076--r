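# Demo pipeline configuration: five synthetic genomes, 200 background genes
# each, one canonical Tad (T4cP) locus and one functional T4aP locus per
# genome, five compositionally alien genes per genome, a conserved flanking
# pair in 4 of 5 genomes, and alien codon usage planted on pilX in 2 of 5
# genomes plus one scattered pilE copy per genome (alien in 2 of 5).
seed: 1
simulate:
  n_genomes: 5
  n_background_genes: 200
  n_alien_genes: 5
  alien_gc_shift: 0.15
  flank_conservation: 0.8
  loci_to_embed:
    - template: T4cP_canonical
      target_identity: 0.8
    - template: T4aP_functional
      target_identity: 0.8
  alien_usage_rates:
    pilX: 0.4
  scattered_pilE:
    per_genome: 1
    alien_rate: 0.4
thresholds:
  min_id: 0.4
  min_cov: 0.6
  max_gap_genes: 5
  min_flags: 3
  ortholog_min_identity: 0.8
  mcl_inflation: 2.0
outgroup: sg01
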