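variant_tsv_cols <- c("chrom", "pos", "refAllele", "altAllele",
                      "ctrl_ref", "ctrl_alt", "exp_ref", "exp_alt")

#' Read a variant allelic count table
#'
#' Reads per-site two-allele read counts for the control and experimental
#' conditions, from either the workflow's TSV schema (`chrom`, `pos`
#' 1-based, `refAllele`, `altAllele`, `ctrl_ref`, `ctrl_alt`, `exp_ref`,
#' `exp_alt`) or a VCF with per-sample allelic depth (`AD`) fields, sample 1
#' = control, sample 2 = experimental (requires the vcfR package).
#' Malformed records are rejected with their line numbers.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return Tibble with internal column names: `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `ctrl_a`, `ctrl_b`, `exp_a`, `exp_b` (reference allele
#'   mapped to a, alternate to b).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") return(read_variant_vcf(path))
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(variant_tsv_cols, header)
  if (length(missing) > 0) {
    abort(paste0("variant table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         refAllele = readr::col_character(),
                         altAllele = readr::col_character(),
                         .default = readr::col_double()))
  counts <- c("ctrl_ref", "ctrl_alt", "exp_ref", "exp_alt")
  bad <- which(Reduce(`|`, lapply(x[counts], function(v) is.na(v) | v < 0)))
  if (length(bad) > 0) {
    abort(sprintf("negative or missing count(s) at data line(s): %s",
                  paste(bad, collapse = ", ")))
  }
  dup <- which(duplicated(paste(x$chrom, x$pos)))
  if (length(dup) > 0) {
    abort(sprintf("duplicate (chrom, pos) at data line(s): %s",
                  paste(dup, collapse = ", ")))
  }
  tibble(
    chrom = x$chrom, pos = x$pos,
    allele_a = as.character(x$refAllele),
    allele_b = as.character(x$altAllele),
    ctrl_a = x$ctrl_ref, ctrl_b = x$ctrl_alt,
    exp_a = x$exp_ref, exp_b = x$exp_alt
  )
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF input requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (ncol(ad) < 2) abort("VCF must carry two samples (control, experimental).")
  split_ad <- function(col) {
    parts <- stringr::str_split_fixed(col, ",", 2)
    list(ref = as.numeric(parts[, 1]), alt = as.numeric(parts[, 2]))
  }
  ctrl <- split_ad(ad[, 1])
  exp <- split_ad(ad[, 2])
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  tibble(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    allele_a = fix$REF, allele_b = fix$ALT,
    ctrl_a = ctrl$ref, ctrl_b = ctrl$alt,
    exp_a = exp$ref, exp_b = exp$alt
  )
}

#' @rdname read_variant_table
#' @param sites Internal-format variant tibble (see return value).
#' @export
write_variant_table <- function(sites, path) {
  out <- tibble(
    chrom = sites$chrom, pos = sites$pos,
    refAllele = sites$allele_a, altAllele = sites$allele_b,
    ctrl_ref = sites$ctrl_a, ctrl_alt = sites$ctrl_b,
    exp_ref = sites$exp_a, exp_alt = sites$exp_b
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read regions from a BED file
#'
#' BED3/4/6, 0-based half-open, tab-separated, no header. Output is sorted
#' by (chrom, start); intervals with `start >= end` are rejected with line
#' numbers.
#'
#' @param path File path.
#' @return Region tibble: `region_id`, `chrom`, `start`, `end`, and
#'   `strand` when a sixth column is present.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  if (ncol(x) < 3) abort("BED needs at least chrom, start, end.")
  bad <- which(x[[2]] >= x[[3]])
  if (length(bad) > 0) {
    abort(sprintf("BED interval with start >= end at line(s): %s",
                  paste(bad, collapse = ", ")))
  }
  out <- tibble(
    region_id = if (ncol(x) >= 4) as.character(x[[4]])
                else sprintf("region%04d", seq_len(nrow(x))),
    chrom = as.character(x[[1]]),
    start = as.numeric(x[[2]]),
    end = as.numeric(x[[3]])
  )
  if (ncol(x) >= 6) out$strand <- as.character(x[[6]])
  arrange(out, .data$chrom, .data$start)
}

#' @rdname read_bed
#' @param regions Region tibble (`region_id`, `chrom`, `start`, `end`,
#'   optional `strand`).
#' @export
write_bed <- function(regions, path) {
  cols <- list(regions$chrom, as.integer(regions$start),
               as.integer(regions$end), regions$region_id)
  if ("strand" %in% names(regions)) {
    cols <- c(cols, list(rep(0L, nrow(regions)), regions$strand))
  }
  readr::write_tsv(as_tibble(setNames(cols, paste0("X", seq_along(cols)))),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read and write bedGraph tracks
#'
#' Four-column bedGraph (chrom, start, end, value), 0-based half-open;
#' values written with six decimals.
#'
#' @param path File path.
#' @return Tibble: `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       show_col_types = FALSE, comment = "#")
  if (any(x$start >= x$end)) abort("bedGraph interval with start >= end.")
  x
}

#' @rdname read_bedgraph
#' @param track Tibble with `chrom`, `start`, `end` and a value column
#'   (named `value`, or pass `value_col`).
#' @param value_col Name of the value column.
#' @export
write_bedgraph <- function(track, path, value_col = "value") {
  out <- tibble(
    chrom = track$chrom,
    start = as.integer(track$start),
    end = as.integer(track$end),
    value = sprintf("%.6f", track[[value_col]])
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read and write contact matrices as plain text
#'
#' Dense format: a header line `# chrom=<name> bin_size=<bp>` followed by a
#' whitespace-separated square matrix. Triplet format: the same header with
#' `format=triplet`, then lines `bin_i bin_j count` (1-based bins; missing
#' pairs are zero; either triangle suffices).
#'
#' @param path File path.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#")) {
    abort("contact matrix file must start with a '# chrom=... bin_size=...' header.")
  }
  hdr <- lines[1]
  get_field <- function(name, default = NULL) {
    m <- stringr::str_match(hdr, paste0(name, "=([^ ]+)"))[, 2]
    if (is.na(m)) default else m
  }
  chrom <- get_field("chrom", "chr")
  bin_size <- as.numeric(get_field("bin_size", "40000"))
  fmt <- get_field("format", "dense")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (fmt == "triplet") {
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    i <- as.integer(parts[, 1])
    j <- as.integer(parts[, 2])
    v <- as.numeric(parts[, 3])
    n <- max(i, j)
    m <- matrix(0, n, n)
    m[cbind(i, j)] <- v
    m[cbind(j, i)] <- v
  } else {
    m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  }
  contact_matrix(m, chrom = chrom, bin_size = bin_size)
}

#' @rdname read_contact_matrix
#' @param cm A [contact_matrix()].
#' @param format `"dense"` or `"triplet"` (upper triangle, non-zero only).
#' @export
write_contact_matrix <- function(cm, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "dense") {
    writeLines(sprintf("# chrom=%s bin_size=%g", cm$chrom, cm$bin_size), con)
    utils::write.table(cm$matrix, con, row.names = FALSE,
                       col.names = FALSE)
  } else {
    writeLines(sprintf("# chrom=%s bin_size=%g format=triplet",
                       cm$chrom, cm$bin_size), con)
    idx <- which(upper.tri(cm$matrix, diag = TRUE) & cm$matrix != 0,
                 arr.ind = TRUE)
    writeLines(sprintf("%d %d %g", idx[, 1], idx[, 2],
                       cm$matrix[idx]), con)
  }
  invisible(path)
}
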