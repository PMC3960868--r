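# Shared fixtures, built once per test run. The full-scale study fixture
# (30 planted genes, 5 x 400 kb contigs, 30% withheld from the CDS track)
# is the package's reference study condition and is also what the
# acceptance script regenerates.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

study_fixture <- function() cached("study", simulate_study(seed = 1L))

study_hmm <- function() {
  cached("hmm", build_profile(study_fixture()$seed_alignment))
}

# profile matching the small fixture's own seed alignment
small_hmm <- function() {
  cached("small_hmm", build_profile(small_fixture()$seed_alignment))
}

# small fixture for fast pipeline tests
small_fixture <- function() {
  cached("small", simulate_study(
    seed = 11L,
    genes_per_group = c(Malpha = 3L, MIKCc = 2L),
    ref_genes_per_group = c(Malpha = 2L, MIKCc = 2L),
    n_contigs = 2L, contig_length = 60000L,
    decoy_gene_count = 12L, withhold_frac = 0.4
  ))
}

# write a fixture to disk and return a filled-in config
fixture_config <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fx$genome$assembly, file.path(dir, "assembly.fa"))
  write_fasta(fx$genome$cds, file.path(dir, "cds.fa"))
  write_fasta(fx$seed_alignment, file.path(dir, "seed_alignment.afa"))
  write_fasta(fx$ref_proteins, file.path(dir, "reference_proteins.faa"))
  readr::write_tsv(fx$refs, file.path(dir, "reference_labels.tsv"))
  readr::write_tsv(fx$genome$annotation, file.path(dir, "annotation.tsv"))
  cfg <- default_config()
  cfg$paths$assembly <- file.path(dir, "assembly.fa")
  cfg$paths$cds <- file.path(dir, "cds.fa")
  cfg$paths$seed_alignment <- file.path(dir, "seed_alignment.afa")
  cfg$paths$annotation <- file.path(dir, "annotation.tsv")
  cfg$paths$references <- file.path(dir, "reference_labels.tsv")
  cfg$paths$reference_proteins <- file.path(dir, "reference_proteins.faa")
  cfg
}

# match recovered gene models to manifest genes by same-strand overlap
match_models_to_truth <- function(models, manifest) {
  vapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    hit <- models$contig_id == m$chromosome & models$strand == m$strand &
      models$start < m$end & models$end > m$start
    if (!any(hit)) NA_character_ else models$gene_id[which(hit)[[1]]]
  }, character(1))
}
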