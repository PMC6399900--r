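#' Genome table of per-site pooled counts
#'
#' The package's canonical site container: a data frame with one row per
#' genomic site and columns `chrom`, `pos` (1-based), `k1`, `r1`, `k2`,
#' `r2` — focal-allele read counts and coverages for the two species —
#' plus optional QC columns `n_alleles` (distinct nucleotide classes
#' observed), `near_indel`, and bias p-values `pv_strand`, `pv_tail`,
#' `pv_baseq`.  The focal allele is the globally minor allele across both
#' pools (ties broken by alphabetical nucleotide order), so polarity is
#' consistent between species, which is all the folded statistics need.
#'
#' @param df Data frame with at least the six core columns.
#' @param n1,n2 Haploid pool sizes of the two species.
#' @param epsilon Assumed sequencing error rate.
#' @param chrom_sizes Optional named vector of chromosome lengths (bp).
#' @return A `genome_table` (also a data frame).
#' @export
genome_table <- function(df, n1 = 40L, n2 = 40L, epsilon = 0.001,
                         chrom_sizes = NULL) {
  need <- c("chrom", "pos", "k1", "r1", "k2", "r2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  for (cc in c("pos", "k1", "r1", "k2", "r2")) df[[cc]] <- as.integer(df[[cc]])
  if (nrow(df)) {
    if (any(df$pos < 1L)) stop("positions must be >= 1")
    if (any(df$k1 < 0L | df$k2 < 0L)) stop("negative counts")
    if (any(df$k1 > df$r1 | df$k2 > df$r2))
      stop("focal count exceeds coverage")
    dpos <- unlist(lapply(split(df$pos, df$chrom), diff), use.names = FALSE)
    if (length(dpos) && any(dpos <= 0L))
      stop("positions must be strictly increasing within each chromosome")
  }
  structure(df, class = c("genome_table", "data.frame"),
            n1 = as.integer(n1), n2 = as.integer(n2),
            epsilon = epsilon, chrom_sizes = chrom_sizes)
}

#' @export
print.genome_table <- function(x, ...) {
  cat(sprintf("Genome table: %d sites on %d sequence(s); pools n1 = %d, n2 = %d, epsilon = %g\n",
              nrow(x), length(unique(x$chrom)), attr(x, "n1"), attr(x, "n2"),
              attr(x, "epsilon")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more sites\n", nrow(x) - 6L))
  invisible(x)
}

.parse_sync_counts <- function(s, path, lineno) {
  parts <- strsplit(s, ":", fixed = TRUE)
  bad <- lengths(parts) != 6L
  if (any(bad))
    stop(sprintf("%s: malformed count string at line %d", path,
                 lineno[which(bad)[1L]]))
  m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 6L,
              byrow = TRUE)
  if (anyNA(m))
    stop(sprintf("%s: non-numeric count at line %d", path,
                 lineno[which(rowSums(is.na(m)) > 0)[1L]]))
  if (any(m < 0))
    stop(sprintf("%s: negative count at line %d", path,
                 lineno[which(rowSums(m < 0) > 0)[1L]]))
  colnames(m) <- c("A", "T", "C", "G", "N", "del")
  m
}

#' Read a site-count table
#'
#' Two dialects are supported.  `simple` is the canonical internal format:
#' whitespace-separated `chrom pos k1 r1 k2 r2` (optionally followed by
#' the QC columns of [genome_table()], recognised by a header line).
#' `sync` is the pool-seq community interchange format: `chrom pos ref`
#' followed by one `A:T:C:G:N:del` count string per sample; the focal
#' allele is taken as the globally minor nucleotide across both samples
#' (alphabetical order breaks ties), coverage is the sum of all count
#' classes, and the number of distinct nucleotides observed is recorded
#' in `n_alleles` for downstream filtering.
#'
#' @param path File to read.
#' @param dialect `"simple"` or `"sync"`.
#' @param n1,n2,epsilon Pool metadata stored on the returned table.
#' @return A [genome_table()].
#' @export
read_site_table <- function(path, dialect = c("simple", "sync"),
                            n1 = 40L, n2 = 40L, epsilon = 0.001) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  header <- length(lines) > 0L && grepl("^chrom\\b", lines[1L])
  if (header && dialect == "simple") {
    ## headered files (as written by write_site_table) may carry QC columns
    df <- utils::read.table(text = lines, header = TRUE,
                            colClasses = c(chrom = "character"))
    return(genome_table(df, n1, n2, epsilon))
  }
  if (header) { lines <- lines[-1L]; lineno <- lineno[-1L] }
  if (length(lines) == 0L)
    return(genome_table(data.frame(chrom = character(), pos = integer(),
                                   k1 = integer(), r1 = integer(),
                                   k2 = integer(), r2 = integer()),
                        n1, n2, epsilon))
  fields <- strsplit(trimws(lines), "\\s+")

  if (dialect == "simple") {
    nf <- lengths(fields)
    if (any(nf < 6L))
      stop(sprintf("%s: expected >= 6 fields at line %d", path,
                   lineno[which(nf < 6L)[1L]]))
    m <- t(vapply(fields, function(f) f[1:6], character(6L)))
    num <- suppressWarnings(matrix(as.integer(m[, 2:6]), ncol = 5L))
    if (anyNA(num))
      stop(sprintf("%s: non-numeric field at line %d", path,
                   lineno[which(rowSums(is.na(num)) > 0)[1L]]))
    df <- data.frame(chrom = m[, 1L], pos = num[, 1L], k1 = num[, 2L],
                     r1 = num[, 3L], k2 = num[, 4L], r2 = num[, 5L])
  } else {
    nf <- lengths(fields)
    if (any(nf < 5L))
      stop(sprintf("%s: expected >= 5 fields at line %d", path,
                   lineno[which(nf < 5L)[1L]]))
    m <- t(vapply(fields, function(f) f[1:5], character(5L)))
    pos <- suppressWarnings(as.integer(m[, 2L]))
    if (anyNA(pos))
      stop(sprintf("%s: non-numeric position at line %d", path,
                   lineno[which(is.na(pos))[1L]]))
    c1 <- .parse_sync_counts(m[, 4L], path, lineno)
    c2 <- .parse_sync_counts(m[, 5L], path, lineno)
    nuc <- c("A", "C", "G", "T")  # alphabetical for tie-breaks
    tot <- c1[, nuc, drop = FALSE] + c2[, nuc, drop = FALSE]
    n_alleles <- rowSums(tot > 0L)
    ## the two most frequent nucleotides; minor = smaller combined count
    focal <- character(nrow(tot))
    for (i in seq_len(nrow(tot))) {
      o <- order(-tot[i, ], seq_along(nuc))  # count desc, alphabetical ties
      focal[i] <- nuc[if (tot[i, o[2L]] > 0L) o[2L] else o[1L]]
    }
    idx <- match(focal, colnames(c1))
    df <- data.frame(chrom = m[, 1L], pos = pos,
                     k1 = c1[cbind(seq_along(idx), idx)],
                     r1 = as.integer(rowSums(c1)),
                     k2 = c2[cbind(seq_along(idx), idx)],
                     r2 = as.integer(rowSums(c2)),
                     n_alleles = as.integer(n_alleles))
  }
  genome_table(df, n1, n2, epsilon)
}

#' Write a genome table as simple TSV
#'
#' Writes the canonical `simple` dialect with a header line, so that
#' [read_site_table()] round-trips the table exactly.
#'
#' @param table A [genome_table()].
#' @param path Output file.
#' @export
write_site_table <- function(table, path) {
  stopifnot(inherits(table, "genome_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write differentiated-region calls as BED
#'
#' 0-based half-open intervals; the name column carries the DR id and the
#' score column is the region's maximum window F_ST scaled by 1000 and
#' clipped to `[0, 1000]`.  Overlapping regions on one chromosome are
#' written as-is but flagged with a warning.
#'
#' @param drs A `dr_calls` object (or data frame with `chrom`, `start`,
#'   `end`, `max_fst`).
#' @param path Output file.
#' @export
write_dr_bed <- function(drs, path) {
  df <- as.data.frame(drs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# differentiated regions (BED, 0-based half-open)", con)
  if (nrow(df) == 0L) return(invisible(path))
  stopifnot(all(df$end > df$start), all(df$start >= 0))
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      warning("overlapping differentiated regions on ", ch)
  }
  score <- pmin(pmax(round(df$max_fst * 1000), 0), 1000)
  name <- if (!is.null(df$name)) df$name else sprintf("DR%d", seq_len(nrow(df)))
  utils::write.table(data.frame(df$chrom, df$start, df$end, name, score),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions written by this package
#'
#' @param path BED file (header comments ignored).
#' @return Data frame with `chrom`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(chrom = vapply(f, `[`, "", 1L),
                    start = as.integer(vapply(f, `[`, "", 2L)),
                    end = as.integer(vapply(f, `[`, "", 3L)))
  if (all(lengths(f) >= 4L)) out$name <- vapply(f, `[`, "", 4L)
  if (all(lengths(f) >= 5L)) out$score <- as.numeric(vapply(f, `[`, "", 5L))
  out
}

#' Write / read window statistics TSV
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open), `n_sites`,
#' `pi_w`, `pi_b`, `fst`.
#'
#' @param windows Window statistics data frame from [scan_windows()].
#' @param path File path.
#' @export
write_window_stats <- function(windows, path) {
  utils::write.table(as.data.frame(windows)[, c("chrom", "start", "end",
                                                "n_sites", "pi_w", "pi_b",
                                                "fst")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_stats
#' @export
read_window_stats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character"))
}

#' Write / read a folded SFS as TSV
#'
#' Two columns: folded class and probability.
#'
#' @param sfs A [folded_sfs()].
#' @param path File path.
#' @export
write_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "folded_sfs"))
  utils::write.table(data.frame(class = as.integer(names(sfs$phi)),
                                probability = as.numeric(sfs$phi)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  n <- 2L * max(df$class)
  folded_sfs(df$probability[order(df$class)], n)
}

#' Record run parameters in a plain-text log
#'
#' Writes `key = value` lines (seed, thresholds, preset names, ...) so a
#' scan is reproducible from its log.
#'
#' @param params Named list of scalar settings.
#' @param path File path.
#' @export
write_run_log <- function(params, path) {
  stopifnot(length(names(params)) == length(params))
  writeLines(c(sprintf("# poolscan run log (%s)",
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               vapply(names(params), function(k)
                 sprintf("%s = %s", k, paste(format(params[[k]]),
                                             collapse = ",")),
                 character(1L))), path)
  invisible(path)
}
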