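#' Read allelic count tables
#'
#' Parses per-sample allelic counts in one of three layouts:
#'
#' * `"long"` — tab-separated with header
#'   `sample_id  gene_id  ref_count  alt_count` (an optional `total_count`
#'   column is validated against `ref + alt`, never trusted).
#' * `"matrix_pair"` — two gene-by-sample matrices (genes as rows, first
#'   column `gene_id`, one column per sample): `path` holds reference counts
#'   and `alt_path` alternate counts. Cells missing from either matrix are
#'   absent records, not zeros.
#' * `"phaser"` — a per-sample variant table in phASER `allelic_counts.txt`
#'   style with at least columns
#'   `contig position variantID refAllele altAllele refCount altCount
#'   totalCount`. Returns variant-level records (see
#'   [aggregate_to_gene_level()]); the sample id is taken from `sample_id`
#'   or, by default, the file's base name.
#'
#' Counts must be non-negative integers; integral floating-point values such
#' as `7.0` are accepted and cast. In every layout the total count is
#' recomputed as `ref_count + alt_count`.
#'
#' @param path Path to the (reference) count table.
#' @param dialect One of `"long"`, `"matrix_pair"`, `"phaser"`.
#' @param alt_path Path to the alternate-count matrix
#'   (`dialect = "matrix_pair"` only).
#' @param sample_id Sample identifier for `dialect = "phaser"`; defaults to
#'   the file name without extension.
#'
#' @return A tibble of gene-level records
#'   (`sample_id, gene_id, ref_count, alt_count, total_count`) for `"long"`
#'   and `"matrix_pair"`, or variant-level records (`sample_id, contig,
#'   position, variant_id, ref_allele, alt_allele, ref_count, alt_count,
#'   total_count`) for `"phaser"`.
#' @seealso [write_ase_counts()], [aggregate_to_gene_level()]
#' @export
read_ase_counts <- function(path,
                            dialect = c("long", "matrix_pair", "phaser"),
                            alt_path = NULL,
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Input file not found: %s", path), class = "aseqc_io_error")
  }
  switch(dialect,
    long = read_long_dialect(path),
    matrix_pair = read_matrix_pair_dialect(path, alt_path),
    phaser = read_phaser_dialect(path, sample_id)
  )
}

read_long_dialect <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  require_columns(tbl, c("sample_id", "gene_id", "ref_count", "alt_count"),
                  path)
  ref <- parse_count_column(tbl$ref_count, "ref_count")
  alt <- parse_count_column(tbl$alt_count, "alt_count")
  out <- tibble::tibble(
    sample_id = as.character(tbl$sample_id),
    gene_id = as.character(tbl$gene_id),
    ref_count = ref,
    alt_count = alt,
    total_count = ref + alt
  )
  if ("total_count" %in% names(tbl)) {
    declared <- parse_count_column(tbl$total_count, "total_count")
    bad <- which(declared != out$total_count)
    if (length(bad) > 0) {
      abort(sprintf(
        "total_count inconsistent with ref_count + alt_count at row %d (%d != %d).",
        bad[1], declared[bad[1]], out$total_count[bad[1]]),
        class = "aseqc_validation_error")
    }
  }
  out
}

read_matrix_pair_dialect <- function(path, alt_path) {
  if (is.null(alt_path)) {
    abort("dialect \"matrix_pair\" requires `alt_path` (the alternate-count matrix).",
          class = "aseqc_format_error")
  }
  if (!file.exists(alt_path)) {
    abort(sprintf("Input file not found: %s", alt_path),
          class = "aseqc_io_error")
  }
  melt <- function(p, value_name) {
    tbl <- readr::read_tsv(p, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    require_columns(tbl, "gene_id", p)
    if (ncol(tbl) < 2) {
      abort(sprintf("Matrix file has no sample columns: %s", p),
            class = "aseqc_format_error")
    }
    long <- tidyr::pivot_longer(tbl, cols = -"gene_id",
                                names_to = "sample_id", values_to = "raw")
    long <- dplyr::filter(long, !is.na(.data$raw), .data$raw != "NA",
                          .data$raw != "")
    long[[value_name]] <- parse_count_column(long$raw, value_name)
    dplyr::select(long, "sample_id", "gene_id", dplyr::all_of(value_name))
  }
  refs <- melt(path, "ref_count")
  alts <- melt(alt_path, "alt_count")
  out <- dplyr::inner_join(refs, alts, by = c("sample_id", "gene_id"))
  dplyr::mutate(out, total_count = .data$ref_count + .data$alt_count)
}

read_phaser_dialect <- function(path, sample_id) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  require_columns(tbl, c("contig", "position", "variantID", "refAllele",
                         "altAllele", "refCount", "altCount", "totalCount"),
                  path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ref <- parse_count_column(tbl$refCount, "refCount")
  alt <- parse_count_column(tbl$altCount, "altCount")
  declared <- parse_count_column(tbl$totalCount, "totalCount")
  bad <- which(declared != ref + alt)
  if (length(bad) > 0) {
    abort(sprintf(
      "totalCount inconsistent with refCount + altCount at row %d.", bad[1]),
      class = "aseqc_validation_error")
  }
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    contig = as.character(tbl$contig),
    position = parse_count_column(tbl$position, "position"),
    variant_id = as.character(tbl$variantID),
    ref_allele = as.character(tbl$refAllele),
    alt_allele = as.character(tbl$altAllele),
    ref_count = ref,
    alt_count = alt,
    total_count = ref + alt
  )
  if ("gene_id" %in% names(tbl)) out$gene_id <- as.character(tbl$gene_id)
  out
}

require_columns <- function(tbl, cols, path) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("File %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "aseqc_format_error")
  }
  invisible(tbl)
}

# Counts arrive as character (or numeric); integral values are cast,
# non-integral or negative values are rejected with the offending row.
parse_count_column <- function(x, name) {
  num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(num) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("Column %s has a non-numeric value at row %d: \"%s\"",
                  name, bad[1], x[bad[1]]),
          class = "aseqc_validation_error")
  }
  frac <- which(is.finite(num) & num != round(num))
  if (length(frac) > 0) {
    abort(sprintf("Column %s has a non-integral value at row %d: %s",
                  name, frac[1], x[frac[1]]),
          class = "aseqc_validation_error")
  }
  neg <- which(num < 0)
  if (length(neg) > 0) {
    abort(sprintf("Column %s has a negative value at row %d: %s",
                  name, neg[1], x[neg[1]]),
          class = "aseqc_validation_error")
  }
  as.integer(round(num))
}

#' Write gene-level allelic counts as a long TSV
#'
#' Emits the `"long"` dialect read by [read_ase_counts()]: columns
#' `sample_id gene_id ref_count alt_count total_count`. The round trip is
#' lossless.
#'
#' @param counts Tibble with at least
#'   `sample_id, gene_id, ref_count, alt_count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ase_counts <- function(counts, path) {
  require_columns(counts, c("sample_id", "gene_id", "ref_count", "alt_count"),
                  "<counts>")
  out <- dplyr::transmute(
    counts,
    sample_id = as.character(.data$sample_id),
    gene_id = as.character(.data$gene_id),
    ref_count = as.integer(.data$ref_count),
    alt_count = as.integer(.data$alt_count),
    total_count = as.integer(.data$ref_count + .data$alt_count)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a variant-to-gene map
#'
#' Accepts either a two-column TSV (`variant_id  gene_id`) or a BED-like
#' four-column interval file (`chrom  start  end  gene_id`, 0-based
#' half-open). The layout is detected from the header / column count.
#'
#' @param path Path to the map file.
#' @return A tibble with columns `variant_id, gene_id` or
#'   `chrom, start, end, gene_id`.
#' @export
read_variant_gene_map <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Map file not found: %s", path), class = "aseqc_io_error")
  }
  fields <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  has_header <- any(c("variant_id", "gene_id", "chrom") %in% fields)
  tbl <- readr::read_tsv(path, col_names = has_header,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!has_header) {
    names(tbl) <- if (ncol(tbl) >= 4) {
      c("chrom", "start", "end", "gene_id", names(tbl)[-(1:4)])
    } else if (ncol(tbl) == 2) {
      c("variant_id", "gene_id")
    } else {
      abort("Variant-gene map must have 2 (id map) or >= 4 (BED) columns.",
            class = "aseqc_format_error")
    }
  }
  if (all(c("variant_id", "gene_id") %in% names(tbl))) {
    return(tibble::tibble(variant_id = tbl$variant_id,
                          gene_id = tbl$gene_id))
  }
  if (all(c("chrom", "start", "end", "gene_id") %in% names(tbl))) {
    return(tibble::tibble(
      chrom = tbl$chrom,
      start = parse_count_column(tbl$start, "start"),
      end = parse_count_column(tbl$end, "end"),
      gene_id = tbl$gene_id
    ))
  }
  abort("Variant-gene map must carry (variant_id, gene_id) or (chrom, start, end, gene_id).",
        class = "aseqc_format_error")
}

#' Aggregate variant-level counts to gene level
#'
#' For each `(sample, gene)` the gene's allele-specific expression is
#' represented by its single most expressed variant — the one with the
#' highest total count. Ties are broken deterministically by lexicographic
#' `(contig, position, variant_id)`. Variants without a gene assignment are
#' dropped and counted in the `n_dropped` attribute (also reported via a
#' message).
#'
#' @param variants Variant-level tibble as returned by
#'   `read_ase_counts(dialect = "phaser")`.
#' @param variant_to_gene A map from [read_variant_gene_map()]: either
#'   `variant_id -> gene_id` pairs, or BED-like gene intervals (0-based
#'   half-open; a variant's 1-based `position` is assigned to a gene when
#'   `start < position <= end`). A variant matching more than one gene is a
#'   validation error.
#'
#' @return A gene-level tibble
#'   (`sample_id, gene_id, ref_count, alt_count, total_count`) with attribute
#'   `n_dropped`.
#' @examples
#' v <- tibble::tibble(
#'   sample_id = "S1", contig = "chr1", position = c(100L, 200L, 300L),
#'   variant_id = c("v1", "v2", "v3"), ref_allele = "A", alt_allele = "G",
#'   ref_count = c(6L, 20L, 5L), alt_count = c(4L, 5L, 3L),
#'   total_count = c(10L, 25L, 8L)
#' )
#' map <- tibble::tibble(variant_id = c("v1", "v2", "v3"), gene_id = "G1")
#' aggregate_to_gene_level(v, map)  # keeps v2, the total-25 variant
#' @export
aggregate_to_gene_level <- function(variants, variant_to_gene) {
  require_columns(variants,
                  c("sample_id", "variant_id", "ref_count", "alt_count"),
                  "<variants>")
  if (nrow(variants) == 0) {
    return(empty_gene_records())
  }
  if (!"contig" %in% names(variants)) variants$contig <- ""
  if (!"position" %in% names(variants)) variants$position <- 0L

  if (all(c("variant_id", "gene_id") %in% names(variant_to_gene))) {
    multi <- variant_to_gene |>
      dplyr::distinct(.data$variant_id, .data$gene_id) |>
      dplyr::count(.data$variant_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(multi) > 0) {
      abort(sprintf("Variant %s maps to multiple genes.",
                    multi$variant_id[1]),
            class = "aseqc_validation_error")
    }
    mapped <- dplyr::left_join(
      dplyr::select(variants, -dplyr::any_of("gene_id")),
      dplyr::distinct(variant_to_gene, .data$variant_id, .data$gene_id),
      by = "variant_id"
    )
  } else if (all(c("chrom", "start", "end", "gene_id")
                 %in% names(variant_to_gene))) {
    mapped <- assign_genes_by_interval(variants, variant_to_gene)
  } else {
    abort("`variant_to_gene` must carry (variant_id, gene_id) or (chrom, start, end, gene_id).",
          class = "aseqc_format_error")
  }

  n_dropped <- sum(is.na(mapped$gene_id))
  mapped <- dplyr::filter(mapped, !is.na(.data$gene_id))
  if (n_dropped > 0) {
    message(sprintf("aggregate_to_gene_level: dropped %d unmapped variant record(s).",
                    n_dropped))
  }
  if (nrow(mapped) == 0) {
    out <- empty_gene_records()
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }

  out <- mapped |>
    dplyr::arrange(.data$sample_id, .data$gene_id,
                   dplyr::desc(.data$total_count),
                   .data$contig, .data$position, .data$variant_id) |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      gene_id = .data$gene_id,
      ref_count = as.integer(.data$ref_count),
      alt_count = as.integer(.data$alt_count),
      total_count = as.integer(.data$ref_count + .data$alt_count)
    )
  attr(out, "n_dropped") <- n_dropped
  out
}

empty_gene_records <- function() {
  out <- tibble::tibble(
    sample_id = character(), gene_id = character(),
    ref_count = integer(), alt_count = integer(), total_count = integer()
  )
  attr(out, "n_dropped") <- 0L
  out
}

# Interval assignment: BED intervals are 0-based half-open [start, end), so a
# 1-based variant position falls inside when start < position <= end.
assign_genes_by_interval <- function(variants, intervals) {
  vt <- dplyr::select(variants, -dplyr::any_of("gene_id"))
  hits <- dplyr::inner_join(
    dplyr::mutate(vt, .row = dplyr::row_number()),
    intervals,
    by = c(contig = "chrom"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$start < .data$position,
                  .data$position <= .data$end) |>
    dplyr::distinct(.data$.row, .data$gene_id)
  multi <- dplyr::count(hits, .data$.row) |> dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    bad <- vt$variant_id[multi$.row[1]]
    abort(sprintf("Variant %s maps to multiple genes.", bad),
          class = "aseqc_validation_error")
  }
  vt$gene_id <- NA_character_
  vt$gene_id[hits$.row] <- hits$gene_id
  vt
}

#' Write cohort QC results
#'
#' Emits two files under a common prefix: `<prefix>_samples.tsv` with one row
#' per sample (`sample_id, n_genes_used, mu_hat, sigma_hat, loglik,
#' converged, pass`, ordered by `sample_id`) and `<prefix>_summary.json` with
#' the cohort threshold report (`q1, median, q3, medcouple, sigma_t, n_pass,
#' n_fail, n_nonconverged`).
#'
#' @param result An `aseqc_qc` object from [qc_cohort()].
#' @param out_prefix Path prefix for the two output files.
#' @return Character vector of the two paths written, invisibly.
#' @seealso [qc_cohort()], [tidy()], [glance()]
#' @export
write_qc_results <- function(result, out_prefix) {
  stopifnot(inherits(result, "aseqc_qc"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) {
    abort(sprintf("Output directory does not exist: %s", dir),
          class = "aseqc_io_error")
  }
  tsv_path <- paste0(out_prefix, "_samples.tsv")
  json_path <- paste0(out_prefix, "_summary.json")

  per_sample <- tidy(result) |>
    dplyr::arrange(.data$sample_id) |>
    dplyr::select("sample_id", "n_genes_used", "mu_hat", "sigma_hat",
                  "loglik", "converged", "pass")
  readr::write_tsv(per_sample, tsv_path, progress = FALSE)

  summary <- as.list(glance(result))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv_path, json_path))
}
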