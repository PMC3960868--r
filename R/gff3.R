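# Minimal GFF3 emission/ingestion for gene models and gene positions.
# Internally everything is 0-based half-open; GFF3 lines are 1-based closed.

# Reads the tab-separated body of a GFF3 file into a tibble with 0-based
# half-open coordinates and the ID/Parent attributes extracted.
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(seqid = character(), source = character(),
                  type = character(), start = integer(), end = integer(),
                  strand = character(), id = character(),
                  parent = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) stop("malformed GFF3 line in ", path)
  m <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    out <- rep(NA_character_, length(attrs))
    found <- grepl(paste0("(^|;)", key, "="), attrs)
    out[found] <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2",
                      attrs[found])
    out
  }
  tibble(
    seqid = m[, 1], source = m[, 2], type = m[, 3],
    start = as.integer(m[, 4]) - 1L, end = as.integer(m[, 5]),
    strand = m[, 7],
    id = attr_get(m[, 9], "ID"),
    parent = attr_get(m[, 9], "Parent")
  )
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/CDS features (1-based closed coordinates, as the format
#' requires).
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path, source = "famscan") {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    gid <- m$gene_id
    lines <- c(
      lines,
      paste(m$contig_id, source, "gene", m$start + 1L, m$end, ".", m$strand,
            ".", paste0("ID=", gid, ";track=", m$source,
                        ";partial=", tolower(m$partial)),
            sep = "\t"),
      paste(m$contig_id, source, "mRNA", m$start + 1L, m$end, ".", m$strand,
            ".", paste0("ID=", gid, ".m1;Parent=", gid), sep = "\t")
    )
    cds <- m$cds_intervals[[1]]
    for (j in seq_len(nrow(cds))) {
      lines <- c(lines, paste(
        m$contig_id, source, "CDS", cds$start[[j]] + 1L, cds$end[[j]], ".",
        m$strand, "0", paste0("ID=", gid, ".cds;Parent=", gid, ".m1"),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene positions from GFF3 or TSV
#'
#' Accepts either a GFF3 file (features of type `gene`, id from the `ID`
#' attribute) or a TSV with columns `gene_id`, `chromosome`, `start`,
#' `end` (0-based half-open) and optionally `strand`.
#'
#' @param path Input path (`.gff`/`.gff3` selects the GFF3 reader).
#' @return A tibble: `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' @export
read_gene_positions <- function(path) {
  if (grepl("\\.gff3?$", path)) {
    g <- read_gff3(path)
    g <- g[g$type == "gene", , drop = FALSE]
    tibble(gene_id = g$id, chromosome = g$seqid,
           start = g$start, end = g$end, strand = g$strand)
  } else {
    pos <- readr::read_tsv(path, show_col_types = FALSE)
    stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(pos)))
    if (!"strand" %in% names(pos)) pos$strand <- "."
    tibble(gene_id = as.character(pos$gene_id),
           chromosome = as.character(pos$chromosome),
           start = as.integer(pos$start), end = as.integer(pos$end),
           strand = pos$strand)
  }
}

#' Add gene ranks along each chromosome
#'
#' The rank is the 1-based order of the gene start within its chromosome
#' across the full gene complement supplied; duplicate-pair classification
#' is defined on rank differences.
#'
#' @param positions Position tibble from [read_gene_positions()].
#' @return The tibble with a `rank` column added.
#' @export
add_gene_ranks <- function(positions) {
  positions |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(rank = rank(.data$start, ties.method = "first")) |>
    dplyr::ungroup()
}
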