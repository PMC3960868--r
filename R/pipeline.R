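# Configuration and the pipeline subcommands: annotate (profile build ->
# CDS-track scan -> genome-track scan -> window extraction -> gene calling
# -> merge), classify (two-stage reference-anchored classification) and
# dupstats (duplication-pattern statistics). Per-stage counts are logged to
# stderr as machine-readable lines: "#stage <name> in=<n> out=<n> dropped=<n>".

#' Default pipeline configuration
#'
#' All knobs in one list: input paths, the permissive scan threshold and
#' the stricter confirmation threshold (the two-stage accept logic), the
#' locus window (300 bp upstream, 19,700 bp downstream of the detected
#' domain-box start, i.e. a 20-kb locus), merge overlap, duplicate-pair
#' gap, profile construction parameters and seeds.
#'
#' @return A named list (class `famscan_config`).
#' @export
default_config <- function() {
  structure(list(
    paths = list(
      assembly = NULL, cds = NULL, seed_alignment = NULL,
      annotation = NULL, references = NULL, reference_proteins = NULL,
      positions = NULL, tree = NULL, species_map = NULL
    ),
    thresholds = list(scan_bits = 10, confirm_bits = 20,
                      min_reciprocal_overlap = 0.5, proximal_max_gap = 10L,
                      min_peptide = 40L, min_orf_codons = 60L),
    window = list(upstream_bp = 300L, downstream_bp = 19700L),
    profile = list(gap_threshold = 0.5, pseudocount_weight = 1.0),
    external_predictor = NULL,
    id_prefix = "gene",
    seed = 1L
  ), class = "famscan_config")
}

#' Read / write a pipeline configuration
#'
#' YAML round trip; unspecified fields fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return For `read_config`, a `famscan_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in names(user)) {
    if (is.list(cfg[[section]]) && is.list(user[[section]])) {
      for (k in names(user[[section]])) cfg[[section]][[k]] <- user[[section]][[k]]
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param config A `famscan_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(config) {
  th <- config$thresholds
  if (!all(is.finite(unlist(th)))) stop("all thresholds must be finite")
  if (config$window$upstream_bp < 0 || config$window$downstream_bp < 0) {
    stop("window sizes must be >= 0")
  }
  structure(config, class = "famscan_config")
}

#' Print the full effective configuration
#'
#' @param config A `famscan_config` (default: the package defaults).
#' @return The config, invisibly.
#' @export
show_config <- function(config = default_config()) {
  cat(yaml::as.yaml(unclass(config)))
  invisible(config)
}

log_stage <- function(stage, n_in, n_out) {
  message(sprintf("#stage %s in=%d out=%d dropped=%d", stage, n_in, n_out,
                  n_in - n_out))
}

#' Annotate a genome: the full two-track pipeline
#'
#' Builds the profile from the seed alignment, scans the CDS-track
#' proteins, scans the six-frame-translated assembly, extracts the locus
#' window around each genomic hit, calls genes (naive built-in caller, or
#' an external predictor when configured), confirms models against the
#' stricter threshold, and merges the two tracks. Writes GFF3, protein
#' FASTA, hit TSV/BED and the QC report when `out_dir` is given.
#'
#' @param config A `famscan_config` with `paths$assembly`, `paths$cds`,
#'   `paths$annotation` (coordinates of the CDS track) and
#'   `paths$seed_alignment` set.
#' @param out_dir Optional output directory.
#' @return A list: `models` (merged gene-model tibble), `qc`, `hmm`,
#'   `cds_hits`, `genome_hits`, `regions`.
#' @export
cmd_annotate <- function(config, out_dir = NULL) {
  for (p in c("assembly", "cds", "seed_alignment", "annotation")) {
    if (is.null(config$paths[[p]]) || !file.exists(config$paths[[p]])) {
      stop("missing input: ", p, call. = FALSE)
    }
  }
  th <- config$thresholds
  seed_aln <- read_fasta(config$paths$seed_alignment, alphabet = "protein")
  seed_aln$seq <- gsub("\\*", "-", seed_aln$seq)  # tolerate '*' gap styles
  hmm <- build_profile(seed_aln,
                       gap_threshold = config$profile$gap_threshold,
                       pseudocount_weight = config$profile$pseudocount_weight)
  assembly <- read_fasta(config$paths$assembly, alphabet = "dna")
  cds <- read_fasta(config$paths$cds, alphabet = "dna")
  annotation <- read_gene_positions(config$paths$annotation)

  # CDS track: translate, scan, confirm, attach genomic coordinates
  proteins <- seq_tbl(cds$id, sub("\\*$", "", translate_cds(cds$seq)),
                      alphabet = "protein")
  cds_hits <- scan_proteins(hmm, proteins, th$scan_bits)
  confirmed <- cds_hits[cds_hits$bit_score >= th$confirm_bits, , drop = FALSE]
  log_stage("cds_scan", nrow(proteins), nrow(cds_hits))
  log_stage("cds_confirm", nrow(cds_hits), nrow(confirmed))
  pos <- annotation[match(confirmed$target_id, annotation$gene_id), ,
                    drop = FALSE]
  if (anyNA(pos$gene_id)) {
    stop("CDS hit without annotation coordinates: ",
         confirmed$target_id[is.na(pos$gene_id)][[1]])
  }
  cds_track <- dplyr::bind_rows(c(list(empty_gene_models()),
    purrr::map(seq_len(nrow(confirmed)), function(i) {
      gene_model_row(pos$chromosome[[i]], pos$start[[i]], pos$end[[i]],
                     pos$strand[[i]],
                     tibble(start = pos$start[[i]], end = pos$end[[i]]),
                     proteins$seq[[match(confirmed$target_id[[i]],
                                         proteins$id)]],
                     "cds_track", partial = FALSE,
                     confirmation_score = confirmed$bit_score[[i]])
    })))

  # genome track: six-frame scan, window extraction, gene calling
  genome_hits <- scan_genome(hmm, assembly, th$scan_bits,
                             min_peptide = th$min_peptide)
  genome_hits <- genome_hits[genome_hits$bit_score >= th$confirm_bits, ,
                             drop = FALSE]
  log_stage("genome_scan", nrow(assembly), nrow(genome_hits))
  regions <- extract_region(genome_hits, assembly,
                            upstream_bp = config$window$upstream_bp,
                            downstream_bp = config$window$downstream_bp)
  genome_track <- dplyr::bind_rows(c(list(empty_gene_models()),
    purrr::map(seq_len(nrow(regions)), function(i) {
      if (!is.null(config$external_predictor)) {
        run_external_predictor(regions[i, ], assembly,
                               config$external_predictor, hmm,
                               confirm_bits = th$confirm_bits)
      } else {
        call_gene_naive(regions[i, ], assembly,
                        min_orf_codons = th$min_orf_codons)
      }
    })))
  log_stage("gene_calls", nrow(regions), nrow(genome_track))
  if (nrow(genome_track)) {
    score <- vapply(genome_track$protein, function(p) {
      viterbi_score(hmm, p)$bit_score
    }, numeric(1), USE.NAMES = FALSE)
    genome_track$confirmation_score <- score
    genome_track <- genome_track[score >= th$confirm_bits, , drop = FALSE]
  }
  log_stage("genome_confirm", nrow(regions), nrow(genome_track))

  models <- merge_gene_sets(cds_track, genome_track,
                            min_reciprocal_overlap = th$min_reciprocal_overlap,
                            id_prefix = config$id_prefix)
  log_stage("merge", nrow(cds_track) + nrow(genome_track), nrow(models))
  qc <- qc_report(models)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_models_gff3(models, file.path(out_dir, "gene_models.gff3"))
    write_fasta(seq_tbl(models$gene_id, models$protein, alphabet = "protein"),
                file.path(out_dir, "proteins.faa"))
    readr::write_tsv(qc, file.path(out_dir, "qc_report.tsv"))
    write_hits_tsv(dplyr::select(genome_hits, -"path"),
                   file.path(out_dir, "genome_hits.tsv"))
    if (nrow(genome_hits)) {
      write_bed(genome_hits, file.path(out_dir, "genome_hits.bed"),
                name_prefix = "hit")
      write_bed(regions, file.path(out_dir, "regions.bed"),
                name_prefix = "region")
    }
    write_profile(hmm, file.path(out_dir, "profile.txt"))
  }
  list(models = models, qc = qc, hmm = hmm, cds_hits = cds_hits,
       genome_hits = genome_hits, regions = regions)
}

#' Classify annotated genes against references
#'
#' Scans the annotated proteins and the reference proteins with the
#' profile, then runs the two-stage type/group classification. Writes the
#' report TSV and the per-type Newick trees when `out_dir` is given.
#'
#' @param config A `famscan_config` with `paths$references` (label TSV) and
#'   `paths$reference_proteins` set.
#' @param proteins Sequence tibble of query proteins (e.g. from
#'   [cmd_annotate()]'s `models`); alternatively set `paths$cds`.
#' @param hmm A `profile_hmm`; built from `paths$seed_alignment` when NULL.
#' @param out_dir Optional output directory.
#' @return The classification tibble (trees in attribute `"trees"`).
#' @export
cmd_classify <- function(config, proteins = NULL, hmm = NULL,
                         out_dir = NULL) {
  if (is.null(config$paths$references)) stop("missing input: references")
  refs <- read_reference_labels(config$paths$references)
  if (nrow(refs) == 0L) stop("empty reference table")
  if (is.null(hmm)) {
    seed_aln <- read_fasta(config$paths$seed_alignment, alphabet = "protein")
    hmm <- build_profile(seed_aln,
                         gap_threshold = config$profile$gap_threshold,
                         pseudocount_weight = config$profile$pseudocount_weight)
  }
  if (is.null(proteins)) {
    cds <- read_fasta(config$paths$cds, alphabet = "dna")
    proteins <- seq_tbl(cds$id, sub("\\*$", "", translate_cds(cds$seq)),
                        alphabet = "protein")
  }
  ref_proteins <- read_fasta(config$paths$reference_proteins,
                             alphabet = "protein")
  all_proteins <- dplyr::bind_rows(proteins,
                                   ref_proteins[!ref_proteins$id %in%
                                                  proteins$id, , drop = FALSE])
  hits <- scan_proteins(hmm, all_proteins, config$thresholds$scan_bits)
  log_stage("classify_scan", nrow(all_proteins), nrow(hits))
  cl <- two_stage_classify(hits, all_proteins, hmm, refs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(as_tibble(cl), file.path(out_dir, "classification.tsv"))
    trees <- attr(cl, "trees")
    for (nm in names(trees)) {
      write_newick(trees[[nm]], file.path(out_dir, paste0("tree_", nm, ".nwk")))
    }
  }
  cl
}

#' Duplication statistics on a labeled tree
#'
#' @param config A `famscan_config` with `paths$tree` (Newick),
#'   `paths$species_map` (TSV gene_id/species) and optionally
#'   `paths$positions` set.
#' @param out_dir Optional output directory.
#' @return A `duplication_report`.
#' @export
cmd_dupstats <- function(config, out_dir = NULL) {
  for (p in c("tree", "species_map")) {
    if (is.null(config$paths[[p]])) stop("missing input: ", p, call. = FALSE)
  }
  tree <- read_newick(config$paths$tree)
  if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
  species_map <- readr::read_tsv(config$paths$species_map,
                                 show_col_types = FALSE,
                                 col_types = readr::cols(.default = "c"))
  missing <- setdiff(tree$tip.label, species_map$gene_id)
  if (length(missing)) stop("leaf without species: ", missing[[1]])
  positions <- if (!is.null(config$paths$positions)) {
    read_gene_positions(config$paths$positions)
  } else NULL
  rep <- duplication_report(tree, species_map, positions,
                            proximal_max_gap = config$thresholds$proximal_max_gap)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    clades_flat <- dplyr::mutate(
      rep$clades, genes = vapply(.data$genes, paste, character(1),
                                 collapse = ","))
    readr::write_tsv(clades_flat, file.path(out_dir, "clades.tsv"))
    readr::write_tsv(rep$histogram, file.path(out_dir, "clade_histogram.tsv"))
    readr::write_tsv(rep$duplications, file.path(out_dir, "duplications.tsv"))
    if (!is.null(rep$pairs)) {
      readr::write_tsv(rep$pairs, file.path(out_dir, "pair_classes.tsv"))
    }
    writeLines(utils::capture.output(print(rep)),
               file.path(out_dir, "summary.txt"))
  }
  rep
}

#' Write a complete synthetic fixture to disk
#'
#' Runs [simulate_study()] and writes every file the other subcommands
#' consume (assembly, CDS track, annotation positions, seed alignment,
#' reference labels and proteins, truth manifest).
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Passed to [simulate_study()].
#' @return The fixture list, invisibly.
#' @export
cmd_simulate <- function(out_dir, seed = 1L, ...) {
  fx <- simulate_study(seed = seed, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fx$genome$assembly, file.path(out_dir, "assembly.fa"))
  write_fasta(fx$genome$cds, file.path(out_dir, "cds.fa"))
  write_fasta(fx$seed_alignment, file.path(out_dir, "seed_alignment.afa"))
  write_fasta(fx$ref_proteins, file.path(out_dir, "reference_proteins.faa"))
  readr::write_tsv(fx$refs, file.path(out_dir, "reference_labels.tsv"))
  readr::write_tsv(fx$genome$annotation, file.path(out_dir, "annotation.tsv"))
  readr::write_tsv(fx$genome$truth_positions,
                   file.path(out_dir, "truth_positions.tsv"))
  readr::write_tsv(dplyr::select(fx$genome$manifest, -"domain", -"protein"),
                   file.path(out_dir, "truth_manifest.tsv"))
  write_newick(fx$family$tree, file.path(out_dir, "true_tree.nwk"))
  invisible(fx)
}
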