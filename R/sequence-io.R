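#' Read a reference genome from FASTA
#'
#' Loads every record of a (possibly multi-record, line-wrapped) FASTA file
#' into an in-memory genome. Sequences are uppercased on read; contig names
#' are the first whitespace-delimited token of each header. Duplicate contig
#' names are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase contig sequences, with class
#'   `editnet_genome`.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop_("FASTA file not found: ", path)
  lines <- readLines(path, n = 50L, warn = FALSE)
  nonempty <- lines[nzchar(trimws(lines))]
  if (length(nonempty) == 0) stop_("empty FASTA file: ", path)
  if (!startsWith(nonempty[1], ">")) {
    first_bad <- which(nzchar(trimws(readLines(path, warn = FALSE))))[1]
    stop_("malformed FASTA (line ", first_bad, " is not a header): ", path)
  }
  dss <- Biostrings::readDNAStringSet(path)
  contigs <- toupper(as.character(dss))
  names(contigs) <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(names(contigs))) {
    dup <- unique(names(contigs)[duplicated(names(contigs))])
    stop_("duplicate contig name(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  if (any(nchar(contigs) == 0)) stop_("FASTA contains an empty record")
  as_genome(contigs)
}

as_genome <- function(contigs) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  structure(toupper(contigs), class = "editnet_genome")
}

#' @export
print.editnet_genome <- function(x, ...) {
  cat("<editnet_genome> ", length(x), " contig(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  for (nm in utils::head(names(x), 10)) {
    cat("  ", nm, ": ", format(nchar(x[[nm]]), big.mark = ","), " bp\n",
        sep = "")
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

# Single-base lookup, 1-based fully-closed coordinates (VCF convention).
genome_base <- function(genome, contig, pos) {
  if (!contig %in% names(genome)) stop_("unknown contig: ", contig)
  substr(genome[[contig]], pos, pos)
}

#' Read candidate SNVs from VCF or TSV
#'
#' Parses a candidate list in VCF 4.x or in a 4-to-6-column tab-separated
#' dialect (`contig  pos  ref  alt  [total_coverage  alt_coverage]`).
#' Multiallelic VCF records are split into independent biallelic candidates;
#' rows that are not SNVs (indels, symbolic alleles) are skipped and counted.
#' Duplicate (contig, pos, ref, alt) records are deduplicated with a warning.
#' Coordinates are 1-based throughout.
#'
#' @param path Path to a VCF (`.vcf`) or TSV file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `total_coverage`, `alt_coverage` (the coverage columns are `NA` when the
#'   input carries no depth information). The number of skipped non-SNV rows
#'   is attached as attribute `n_skipped`.
#' @export
read_candidates <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("candidate file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  out <- if (format == "vcf") read_candidates_vcf(path) else read_candidates_tsv(path)
  dup <- duplicated(paste(out$contig, out$pos, out$ref, out$alt))
  if (any(dup)) {
    warning(sum(dup), " duplicate candidate record(s) removed", call. = FALSE)
    skipped <- attr(out, "n_skipped")
    out <- out[!dup, , drop = FALSE]
    attr(out, "n_skipped") <- skipped
  }
  out
}

read_candidates_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_candidates())
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    stop_("unparseable POS at VCF data row ", which(is.na(pos))[1])
  }
  total <- rep(NA_integer_, nrow(fix))
  altdp <- rep(NA_integer_, nrow(fix))
  info_dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))
  if (!all(is.na(info_dp))) total <- info_dp
  if (nrow(vcf@gt %||% matrix(nrow = 0, ncol = 0)) > 0 && ncol(vcf@gt) >= 2) {
    ad <- tryCatch(vcfR::extract.gt(vcf, "AD")[, 1], error = function(e) NULL)
    if (!is.null(ad)) {
      parts <- strsplit(ad, ",", fixed = TRUE)
      refd <- suppressWarnings(vapply(parts, function(p) as.integer(p[1]), 1L))
      ad2 <- suppressWarnings(vapply(parts, function(p) as.integer(p[2]), 1L))
      altdp <- ifelse(is.na(ad2), NA_integer_, ad2)
      tot_ad <- refd + ad2
      total <- ifelse(is.na(total), tot_ad, total)
    }
    dp_gt <- tryCatch(vcfR::extract.gt(vcf, "DP")[, 1], error = function(e) NULL)
    if (!is.null(dp_gt)) {
      dp_gt <- suppressWarnings(as.integer(dp_gt))
      total <- ifelse(is.na(total), dp_gt, total)
    }
  }
  rows <- tibble::tibble(
    contig = fix$CHROM, pos = pos, ref = toupper(fix$REF),
    alt = toupper(fix$ALT), total_coverage = total, alt_coverage = altdp
  )
  # split multiallelic ALT, then keep only true SNVs
  rows <- tidyr::separate_rows(rows, "alt", sep = ",")
  is_snv <- nchar(rows$ref) == 1 & nchar(rows$alt) == 1 &
    rows$ref %in% BASES & rows$alt %in% BASES & rows$ref != rows$alt
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    message("read_candidates: skipped ", n_skipped, " non-SNV allele(s)")
  }
  out <- rows[is_snv, , drop = FALSE]
  attr(out, "n_skipped") <- n_skipped
  out
}

read_candidates_tsv <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (nrow(raw) == 0) return(empty_candidates())
  # tolerate a header line (second column not numeric)
  if (is.na(suppressWarnings(as.integer(raw[1, 2])))) {
    raw <- raw[-1, , drop = FALSE]
    if (nrow(raw) == 0) return(empty_candidates())
  }
  if (ncol(raw) < 4) stop_("TSV candidate file needs at least 4 columns")
  pos <- suppressWarnings(as.integer(raw[[2]]))
  if (anyNA(pos)) stop_("unparseable position at TSV row ", which(is.na(pos))[1])
  total <- if (ncol(raw) >= 5) suppressWarnings(as.integer(raw[[5]])) else NA_integer_
  altc <- if (ncol(raw) >= 6) suppressWarnings(as.integer(raw[[6]])) else NA_integer_
  rows <- tibble::tibble(
    contig = as.character(raw[[1]]), pos = pos,
    ref = toupper(as.character(raw[[3]])), alt = toupper(as.character(raw[[4]])),
    total_coverage = total, alt_coverage = altc
  )
  is_snv <- nchar(rows$ref) == 1 & nchar(rows$alt) == 1 &
    rows$ref %in% BASES & rows$alt %in% BASES & rows$ref != rows$alt
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    message("read_candidates: skipped ", n_skipped, " non-SNV row(s)")
  }
  out <- rows[is_snv, , drop = FALSE]
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_candidates <- function() {
  out <- tibble::tibble(
    contig = character(), pos = integer(), ref = character(),
    alt = character(), total_coverage = integer(), alt_coverage = integer()
  )
  attr(out, "n_skipped") <- 0L
  out
}

#' Filter candidates by read coverage
#'
#' Retains candidates with total read coverage at or above `min_total` and
#' supporting (alternate-allele) read coverage at or above `min_alt`. The
#' defaults match the depth filter commonly applied before editing-site
#' calling: total coverage >= 5 and supporting coverage >= 3.
#'
#' @param candidates Candidate tibble (see [read_candidates()]).
#' @param min_total,min_alt Nonnegative integer thresholds.
#' @return The filtered tibble, original order preserved.
#' @export
coverage_filter <- function(candidates, min_total = 5, min_alt = 3) {
  if (min_total < 0 || min_alt < 0) stop_("coverage thresholds must be nonnegative")
  if (nrow(candidates) == 0) return(candidates)
  if (anyNA(candidates$total_coverage) || anyNA(candidates$alt_coverage)) {
    stop_("coverage_filter requires total_coverage and alt_coverage on every candidate")
  }
  dplyr::filter(candidates,
                .data$total_coverage >= min_total,
                .data$alt_coverage >= min_alt)
}

#' Extract sequence windows centred on candidate SNVs
#'
#' For each candidate, takes the `2 * flank + 1` bases of the reference
#' centred on the candidate position (reference strand, 1-based). Positions
#' beyond a contig end are padded with `N` so the window width is always
#' exactly `2 * flank + 1`.
#'
#' @param genome An `editnet_genome` from [read_reference()].
#' @param candidates Candidate tibble with `contig`, `pos`, `ref`, `alt`.
#' @param flank Nonnegative number of bases on each side (201-bp full input
#'   corresponds to `flank = 100`; the two model scales use 50 and 20).
#' @return The candidate tibble with added columns `seq` (the window string)
#'   and `centre_ref` (the reference base actually at the candidate position).
#' @export
extract_windows <- function(genome, candidates, flank) {
  if (!is_count(flank)) stop_("flank must be a nonnegative integer")
  unknown <- setdiff(unique(candidates$contig), names(genome))
  if (length(unknown) > 0) {
    stop_("unknown contig(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, seq = character(), centre_ref = character()))
  }
  lens <- nchar(genome)[candidates$contig]
  start <- candidates$pos - flank
  end <- candidates$pos + flank
  core <- substr(genome[candidates$contig], pmax(start, 1L), pmin(end, lens))
  pad_l <- pmax(1L - start, 0L)
  pad_r <- pmax(end - lens, 0L)
  seqs <- paste0(strrep("N", pad_l), core, strrep("N", pad_r))
  dplyr::mutate(candidates,
                seq = unname(seqs),
                centre_ref = substr(.data$seq, flank + 1L, flank + 1L))
}

#' Classify candidate mismatch types
#'
#' Tags each candidate with its ordered ref-to-alt mismatch type (one of the
#' 12 possible pairs over A, C, G, T) and whether it is the A-to-I signature.
#' A-to-I editing (adenosine deaminated to inosine, read as guanosine) shows
#' up as an A>G mismatch on the reference strand; with
#' `collapse_revcomp_a2i = TRUE`, T>C is additionally counted as A-to-I, for
#' candidate lists produced by unstranded callers.
#'
#' @param candidates Candidate tibble with `ref` and `alt` columns.
#' @param collapse_revcomp_a2i Also treat T>C as A-to-I (default `FALSE`).
#' @return The tibble with added columns `mismatch` (e.g. `"A>G"`) and
#'   `is_a_to_i`.
#' @export
classify_mismatch <- function(candidates, collapse_revcomp_a2i = FALSE) {
  bad <- candidates$ref == candidates$alt |
    !(candidates$ref %in% BASES) | !(candidates$alt %in% BASES)
  if (any(bad)) stop_("invalid ref/alt pair at row ", which(bad)[1])
  mm <- paste0(candidates$ref, ">", candidates$alt)
  a2i <- mm == "A>G" | (collapse_revcomp_a2i & mm == "T>C")
  dplyr::mutate(candidates,
                mismatch = factor(mm, levels = mismatch_types()),
                is_a_to_i = a2i)
}

#' The 12 ordered mismatch types
#'
#' @return Character vector of the 12 ref>alt pairs over A, C, G, T.
#' @export
mismatch_types <- function() {
  pairs <- expand.grid(ref = BASES, alt = BASES, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  pairs <- pairs[order(pairs$ref, pairs$alt), ]
  paste0(pairs$ref, ">", pairs$alt)
}

#' Canonical site key
#'
#' The (contig, pos, ref, alt) key string used wherever site sets are
#' compared or matched.
#'
#' @param x A site tibble with `contig`, `pos`, `ref`, `alt` columns.
#' @return A character vector of keys, one per row.
#' @export
site_key <- function(x) {
  if (length(x$pos) == 0) return(character(0))
  paste0(x$contig, ":", x$pos, ":", x$ref, ">", x$alt)
}
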