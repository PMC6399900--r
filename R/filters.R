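#' Site-filter configuration
#'
#' QC thresholds applied to a [genome_table()] before inference.  Three
#' named coverage presets mirror the three analyses the pipeline runs:
#' `scan` (20-200x in both species; the genome scan), `sfs` (80-200x; SFS
#' estimation), `sitefst` (>= 40x in both species; the per-site F_ST set).
#'
#' @param preset One of `"scan"`, `"sfs"`, `"sitefst"`, or `"none"`.
#' @param min_coverage,max_coverage Per-species read-depth bounds;
#'   defaults come from the preset.
#' @param indel_mask_radius Sites within this many bp of an indel are
#'   removed (default 9).
#' @param max_allele_classes Sites showing more than this many distinct
#'   nucleotides are removed (default 2, i.e. sites with >= 3 nucleotides
#'   are dropped).
#' @param strand_bias_p,tail_distance_p,baseq_bias_p Lower p-value
#'   thresholds for the optional bias annotations.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(preset = c("scan", "sfs", "sitefst", "none"),
                          min_coverage = NULL, max_coverage = NULL,
                          indel_mask_radius = 9L, max_allele_classes = 2L,
                          strand_bias_p = 1e-4, tail_distance_p = 1e-4,
                          baseq_bias_p = 1e-100) {
  preset <- match.arg(preset)
  cov <- switch(preset,
                scan    = c(20, 200),
                sfs     = c(80, 200),
                sitefst = c(40, Inf),
                none    = c(1, Inf))
  if (is.null(min_coverage)) min_coverage <- cov[1L]
  if (is.null(max_coverage)) max_coverage <- cov[2L]
  stopifnot(min_coverage > 0, min_coverage <= max_coverage,
            indel_mask_radius >= 0)
  structure(list(preset = preset, min_coverage = min_coverage,
                 max_coverage = max_coverage,
                 indel_mask_radius = as.integer(indel_mask_radius),
                 max_allele_classes = as.integer(max_allele_classes),
                 strand_bias_p = strand_bias_p,
                 tail_distance_p = tail_distance_p,
                 baseq_bias_p = baseq_bias_p),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(
    "Site filters [%s]: coverage %g-%g in both species, indel mask +/-%d bp, <=%d allele classes\n",
    x$preset, x$min_coverage, x$max_coverage, x$indel_mask_radius,
    x$max_allele_classes))
  invisible(x)
}

#' Apply site-level QC filters
#'
#' Removes, in order: sites within `indel_mask_radius` bp of a supplied
#' indel position (the union over species), sites where more than
#' `max_allele_classes` nucleotides were observed, sites outside the
#' coverage bounds in either species, and sites whose recorded bias
#' p-values fall below their thresholds.  Filters whose annotation
#' columns are absent are skipped (with a message); the input table is
#' never modified.
#'
#' @param table A [genome_table()].
#' @param cfg A [filter_config()].
#' @param indel_positions Optional indel side-channel: a data frame with
#'   `chrom` and `pos` (1-based), or a named list of integer position
#'   vectors per chromosome.
#' @param quiet Suppress the skipped-filter messages.
#' @return A filtered [genome_table()].
#' @export
apply_site_filters <- function(table, cfg, indel_positions = NULL,
                               quiet = FALSE) {
  stopifnot(inherits(table, "genome_table"), inherits(cfg, "filter_config"))
  keep <- rep(TRUE, nrow(table))

  if (!is.null(indel_positions)) {
    if (is.data.frame(indel_positions))
      indel_positions <- split(indel_positions$pos, indel_positions$chrom)
    rad <- cfg$indel_mask_radius
    for (ch in intersect(names(indel_positions), unique(table$chrom))) {
      ip <- sort(unique(as.integer(indel_positions[[ch]])))
      sel <- which(table$chrom == ch)
      ## nearest indel within radius
      idx <- findInterval(table$pos[sel], ip)
      lo <- ifelse(idx >= 1L, ip[pmax(idx, 1L)], -Inf)
      hi <- ifelse(idx < length(ip), ip[pmin(idx + 1L, length(ip))], Inf)
      near <- (table$pos[sel] - lo) <= rad | (hi - table$pos[sel]) <= rad
      keep[sel[near]] <- FALSE
    }
  }

  if (!is.null(table$n_alleles)) {
    keep <- keep & table$n_alleles <= cfg$max_allele_classes
  } else if (!quiet) {
    message("no n_alleles column; allele-class filter skipped")
  }

  keep <- keep &
    table$r1 >= cfg$min_coverage & table$r1 <= cfg$max_coverage &
    table$r2 >= cfg$min_coverage & table$r2 <= cfg$max_coverage

  if (!is.null(table$near_indel)) keep <- keep & !table$near_indel

  pvmap <- c(pv_strand = "strand_bias_p", pv_tail = "tail_distance_p",
             pv_baseq = "baseq_bias_p")
  for (col in names(pvmap)) {
    if (!is.null(table[[col]])) {
      keep <- keep & !(!is.na(table[[col]]) &
                         table[[col]] < cfg[[pvmap[[col]]]])
    } else if (!quiet) {
      message("no ", col, " column; ", pvmap[[col]], " filter skipped")
    }
  }

  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("n1", "n2", "epsilon", "chrom_sizes")] <-
    attributes(table)[c("n1", "n2", "epsilon", "chrom_sizes")]
  class(out) <- class(table)
  out
}

#' Drop sites with low total minor-allele frequency
#'
#' Robustness re-run helper: removes sites whose estimated minor-allele
#' frequency in the combined dataset (the coverage-weighted pooled read
#' fraction, error-corrected) is at or below `min_maf`.  Rare alleles
#' are where Pool-seq frequency estimates are least accurate, so a
#' stable scan should survive this filter unchanged.
#'
#' @param table A [genome_table()].
#' @param min_maf Minor-allele-frequency threshold (default 0.05;
#'   sites with MAF <= this are removed).
#' @param epsilon Error rate used for the correction (defaults to the
#'   table's).
#' @return A filtered [genome_table()].
#' @export
filter_maf <- function(table, min_maf = 0.05, epsilon = NULL) {
  stopifnot(inherits(table, "genome_table"), min_maf >= 0, min_maf < 0.5)
  if (is.null(epsilon)) epsilon <- attr(table, "epsilon")
  tot <- (table$k1 + table$k2) / pmax(table$r1 + table$r2, 1L)
  p <- pmin(pmax((tot - epsilon) / (1 - 2 * epsilon), 0), 1)
  maf <- pmin(p, 1 - p)
  out <- table[maf > min_maf, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("n1", "n2", "epsilon", "chrom_sizes")] <-
    attributes(table)[c("n1", "n2", "epsilon", "chrom_sizes")]
  class(out) <- class(table)
  out
}
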