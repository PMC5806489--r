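# Core containers and interval algebra. All coordinates are 0-based,
# half-open [start, end) -- the BED convention -- everywhere inside the
# package; 1-based input dialects are converted at the reader boundary.

#' Define a genome layout
#'
#' A genome layout maps chromosome names to lengths in bp. It is the frame
#' against which all interval sets and methylation calls are validated.
#'
#' @param lengths Named numeric vector of chromosome lengths (bp), all > 0,
#'   names unique.
#' @return A named numeric vector of class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(lengths) {
  if (!is.numeric(lengths) || length(lengths) == 0)
    stop("'lengths' must be a non-empty numeric vector")
  nm <- names(lengths)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("every chromosome length must be named")
  if (anyDuplicated(nm))
    stop("duplicate chromosome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be finite and > 0")
  structure(as.numeric(lengths), names = nm, class = "genome_layout")
}

#' Read a chrom-sizes file
#'
#' @param path Two-column tab-separated file: chromosome name, length in bp.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(stats::setNames(df$length, df$chrom))
}

#' Construct a set of genomic intervals
#'
#' The generic container for CpG islands, tsDMRs, ChIP peaks, TF binding
#' sites, super-enhancers and TSS annotations. Coordinates are 0-based
#' half-open; records are validated and sorted by (chrom, start).
#'
#' @param chrom Character vector of chromosome names (or a data.frame with
#'   columns `chrom`, `start`, `end` and optionally `name`, `score`,
#'   `strand`, in which case the remaining arguments are ignored).
#' @param start,end Integer-like start (inclusive) / end (exclusive)
#'   coordinates, `0 <= start < end`.
#' @param name,score,strand Optional per-record annotation columns.
#' @param layout Optional [genome_layout()]; when given, chromosomes must be
#'   present in it and `end` must not exceed the chromosome length.
#' @return A data.frame of class `interval_set`.
#' @export
interval_set <- function(chrom, start = NULL, end = NULL, name = NULL,
                         score = NULL, strand = NULL, layout = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  } else {
    df <- data.frame(chrom = as.character(chrom),
                     start = as.numeric(start),
                     end = as.numeric(end),
                     stringsAsFactors = FALSE)
    if (!is.null(name)) df$name <- as.character(name)
    if (!is.null(score)) df$score <- as.numeric(score)
    if (!is.null(strand)) df$strand <- as.character(strand)
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  validate_intervals(df, layout)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

validate_intervals <- function(df, layout = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$chrom))
    stop("interval coordinates must not contain NA")
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at record ", bad[1], ": ",
         df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]])
  if (!is.null(layout)) {
    unknown <- setdiff(unique(df$chrom), names(layout))
    if (length(unknown))
      stop("chromosome(s) absent from genome layout: ",
           paste(unknown, collapse = ", "))
    over <- which(df$end > unname(layout[df$chrom]))
    if (length(over))
      stop("interval exceeds chromosome length at record ", over[1], ": ",
           df$chrom[over[1]], ":", df$start[over[1]], "-", df$end[over[1]])
  }
  invisible(df)
}

# IRanges helpers: shift 0-based half-open to 1-based closed
.ir <- function(start, end) IRanges::IRanges(start = start + 1, end = end)
.ir_df <- function(df) .ir(df$start, df$end)
.from_ir <- function(ir) {
  data.frame(start = as.numeric(IRanges::start(ir)) - 1,
             end = as.numeric(IRanges::end(ir)))
}

# union-merge intervals of one set, per chromosome; bookended intervals merge
interval_union <- function(x) {
  if (nrow(x) == 0) return(interval_set(x[, c("chrom", "start", "end")]))
  parts <- lapply(split(x, x$chrom), function(d) {
    r <- IRanges::reduce(.ir_df(d))
    cbind(chrom = d$chrom[1], .from_ir(r))
  })
  out <- do.call(rbind, parts)
  interval_set(out)
}

.has_overlaps <- function(df) {
  any(vapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])
  }, logical(1)))
}

#' Read a BED file
#'
#' Accepts 3+ column BED (chrom, start, end, optional name, optional score).
#' Overlapping records within the file are union-merged with a warning,
#' because downstream coverage arithmetic assumes disjoint sets; pass
#' `merge_overlaps = FALSE` to keep them (e.g. for TSS annotations).
#'
#' @param path Path to a tab-separated BED3/4/5 file.
#' @param expects_score If `TRUE`, require a 5th (score) column.
#' @param layout Optional [genome_layout()] for bounds checking.
#' @param merge_overlaps Union-merge overlapping records (default `TRUE`).
#' @return An [interval_set()].
#' @export
read_bed <- function(path, expects_score = FALSE, layout = NULL,
                     merge_overlaps = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(interval_set(data.frame(chrom = character(), start = numeric(),
                                   end = numeric())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (expects_score) 5L else 3L
  bad <- which(nf < need)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": expected >= ", need,
         " tab-separated fields, got ", nf[bad[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": empty or negative interval ",
         chrom[bad[1]], ":", start[bad[1]], "-", end[bad[1]])
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (any(nf >= 4L))
    df$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  if (any(nf >= 5L)) {
    df$score <- suppressWarnings(
      as.numeric(vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")))
    if (expects_score && anyNA(df$score))
      stop("malformed BED line ", lineno[which(is.na(df$score))[1]],
           ": non-numeric score")
  }
  x <- interval_set(df, layout = layout)
  if (merge_overlaps && .has_overlaps(x)) {
    warning("overlapping intervals in ", path, " were union-merged")
    x <- interval_union(x)
  }
  x
}

#' Write an interval set as BED
#'
#' @param x An [interval_set()] (or compatible data.frame).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$score)) {
    cols <- c(cols, list(if (is.null(x$name)) rep(".", nrow(x)) else x$name,
                         x$score))
  } else if (!is.null(x$name)) {
    cols <- c(cols, list(x$name))
  }
  df <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct per-CpG methylation calls
#'
#' @param chrom Character chromosome names (or a data.frame with columns
#'   `chrom`, `pos`, `meth`, `total`).
#' @param pos 0-based bp position of the CpG (plus-strand C).
#' @param meth,total Methylated and total read counts, `0 <= meth <= total`.
#' @param layout Optional [genome_layout()] for validation.
#' @return A data.frame of class `methyl_calls`, sorted by (chrom, pos),
#'   positions unique within a chromosome.
#' @export
methyl_calls <- function(chrom, pos = NULL, meth = NULL, total = NULL,
                         layout = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "pos", "meth", "total") %in% names(df)))
  } else {
    df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                     meth = as.numeric(meth), total = as.numeric(total),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df)) {
    if (any(df$meth < 0) || any(df$total < df$meth))
      stop("methylation calls require 0 <= meth <= total; violated at record ",
           which(df$meth < 0 | df$total < df$meth)[1])
    if (!is.null(layout)) {
      unknown <- setdiff(unique(df$chrom), names(layout))
      if (length(unknown))
        stop("chromosome(s) absent from genome layout: ",
             paste(unknown, collapse = ", "))
    }
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    dup <- duplicated(df[, c("chrom", "pos")])
    if (any(dup))
      stop("duplicate CpG position: ", df$chrom[dup][1], ":", df$pos[dup][1])
  }
  rownames(df) <- NULL
  class(df) <- c("methyl_calls", "data.frame")
  df
}

#' Read per-CpG methylation calls
#'
#' Two dialects are supported. `"bedgraph-counts"` is five columns
#' (chrom, start, end, methylated count, total count), 0-based. `"cpg-report"`
#' is the Bismark-style per-strand report (chrom, 1-based position, strand,
#' methylated count, unmethylated count, optional context column, ignored);
#' the two strands of one CpG are merged into a single strandless site keyed
#' by the plus-strand C position (counts summed), then shifted to 0-based.
#'
#' @param path Input path.
#' @param dialect `"bedgraph-counts"` or `"cpg-report"`.
#' @param layout Optional [genome_layout()].
#' @return A [methyl_calls()] object.
#' @export
read_methyl_calls <- function(path, dialect = c("bedgraph-counts", "cpg-report"),
                              layout = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "bedgraph-counts") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = c("character", "numeric", "numeric",
                                           "numeric", "numeric"))
    names(df) <- c("chrom", "start", "end", "meth", "total")
    return(methyl_calls(data.frame(chrom = df$chrom, pos = df$start,
                                   meth = df$meth, total = df$total),
                        layout = layout))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 5)
    stop("cpg-report requires >= 5 columns (chrom, pos, strand, meth, unmeth)")
  chrom <- as.character(raw[[1]])
  pos1 <- as.numeric(raw[[2]])
  strand <- as.character(raw[[3]])
  meth <- as.numeric(raw[[4]])
  unmeth <- as.numeric(raw[[5]])
  if (!all(strand %in% c("+", "-")))
    stop("cpg-report strand column must be '+' or '-'")
  if (any(meth < 0) || any(unmeth < 0))
    stop("negative counts in cpg-report")
  # key each row by its plus-strand C: minus-strand G sits one bp downstream
  cpos <- ifelse(strand == "-", pos1 - 1, pos1)
  key <- paste(chrom, cpos)
  m <- rowsum(meth, key, reorder = FALSE)
  t <- rowsum(meth + unmeth, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(chrom = chrom[first],
                    pos = cpos[first] - 1,  # 1-based -> 0-based
                    meth = as.numeric(m[match(key[first], rownames(m)), 1]),
                    total = as.numeric(t[match(key[first], rownames(t)), 1]),
                    stringsAsFactors = FALSE)
  out <- out[out$total > 0, , drop = FALSE]
  methyl_calls(out, layout = layout)
}

#' Write methylation calls as bedGraph-with-counts
#'
#' Five-column (chrom, start, end, meth, total) with each CpG a 1-bp record.
#' @param x A [methyl_calls()] object.
#' @param path Output path.
#' @export
write_methyl_calls <- function(x, path) {
  df <- data.frame(x$chrom,
                   format(x$pos, scientific = FALSE, trim = TRUE),
                   format(x$pos + 1, scientific = FALSE, trim = TRUE),
                   x$meth, x$total)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep intervals strictly longer than a minimum length
#'
#' Strict inequality: an interval of exactly `min_len` bp is dropped (e.g.
#' "large peaks > 5 kb, the minimal length of DMVs").
#'
#' @param x An [interval_set()].
#' @param min_len Minimum length in bp (> 0).
#' @return The filtered set, order preserved.
#' @export
filter_by_length <- function(x, min_len) {
  stopifnot(min_len > 0)
  out <- x[(x$end - x$start) > min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interval algebra: subtract, intersect, coverage fraction
#'
#' `interval_subtract(a, b)` returns, for each record of `a`, the maximal
#' sub-intervals not covered by `b`. `interval_intersect(a, b)` returns the
#' covered sub-intervals. `coverage_fraction(a, b)` returns, per record of
#' `a`, the fraction of its bp covered by `b`, in \[0, 1\]. Overlapping `b`
#' intervals are union-merged before computing, so results do not double
#' count. Together, subtract and intersect partition each `a` record.
#'
#' @param a,b [interval_set()] objects. Annotation columns of `a` (`name`,
#'   `score`) are propagated to its sub-intervals.
#' @return An `interval_set` (subtract/intersect) or a numeric vector with
#'   one fraction per record of `a` (coverage_fraction).
#' @export
interval_subtract <- function(a, b) .interval_clip(a, b, keep = "outside")

#' @rdname interval_subtract
#' @export
interval_intersect <- function(a, b) .interval_clip(a, b, keep = "inside")

.interval_clip <- function(a, b, keep) {
  empty <- a[0, , drop = FALSE]
  if (nrow(a) == 0) return(interval_set(as.data.frame(empty)))
  bu <- lapply(split(b, b$chrom), function(d) IRanges::reduce(.ir_df(d)))
  rows <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    rec <- .ir(a$start[i], a$end[i])
    bc <- bu[[a$chrom[i]]]
    piece <- if (is.null(bc)) {
      if (keep == "outside") rec else IRanges::IRanges()
    } else if (keep == "outside") {
      IRanges::setdiff(rec, bc)
    } else {
      IRanges::intersect(rec, bc)
    }
    if (length(piece)) {
      d <- cbind(chrom = a$chrom[i], .from_ir(piece))
      for (col in intersect(c("name", "score", "strand"), names(a)))
        d[[col]] <- a[[col]][i]
      rows[[i]] <- d
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(interval_set(as.data.frame(empty)))
  interval_set(do.call(rbind, rows))
}

#' @rdname interval_subtract
#' @export
coverage_fraction <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  out <- numeric(nrow(a))
  bu <- lapply(split(b, b$chrom), function(d) IRanges::reduce(.ir_df(d)))
  idx <- split(seq_len(nrow(a)), a$chrom)
  for (chr in names(idx)) {
    i <- idx[[chr]]
    bc <- bu[[chr]]
    if (is.null(bc) || length(bc) == 0) next
    air <- .ir(a$start[i], a$end[i])
    hits <- IRanges::findOverlaps(air, bc)
    if (length(hits) == 0) next
    q <- S4Vectors::queryHits(hits)
    w <- IRanges::width(IRanges::pintersect(air[q], bc[S4Vectors::subjectHits(hits)]))
    covered <- rowsum(w, q)
    out[i[as.integer(rownames(covered))]] <- covered[, 1]
  }
  out / (a$end - a$start)
}

#' Construct an expression matrix with a sample-to-lineage map
#'
#' @param fpkm Numeric gene x sample matrix of FPKM values (>= 0), with
#'   row (gene) and column (sample) names.
#' @param lineage Named character vector mapping every sample (column of
#'   `fpkm`) to a lineage label.
#' @return A list of class `expression_matrix` with elements `fpkm`,
#'   `lineage` and `lineages` (the ordered unique lineage labels).
#' @export
expression_matrix <- function(fpkm, lineage) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm)))
    stop("'fpkm' needs gene rownames and sample colnames")
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM values must be >= 0")
  missing <- setdiff(colnames(fpkm), names(lineage))
  if (length(missing))
    stop("sample(s) without a lineage assignment: ",
         paste(missing, collapse = ", "))
  lineage <- lineage[colnames(fpkm)]
  structure(list(fpkm = fpkm, lineage = lineage,
                 lineages = unique(unname(lineage))),
            class = "expression_matrix")
}

#' Read an expression matrix and its lineage map from TSV
#'
#' @param fpkm_path TSV with header row of sample ids and gene ids in the
#'   first column.
#' @param lineage_path Two-column TSV (sample, lineage), no header.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(fpkm_path, lineage_path) {
  fpkm <- utils::read.table(fpkm_path, sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE)
  map <- utils::read.table(lineage_path, sep = "\t", header = FALSE,
                           col.names = c("sample", "lineage"),
                           colClasses = "character")
  expression_matrix(as.matrix(fpkm), stats::setNames(map$lineage, map$sample))
}

#' Per-lineage mean expression
#'
#' Unweighted mean FPKM over the samples of each lineage.
#'
#' @param expr An [expression_matrix()].
#' @return A gene x lineage numeric matrix.
#' @export
lineage_means <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  out <- matrix(NA_real_, nrow(expr$fpkm), length(expr$lineages),
                dimnames = list(rownames(expr$fpkm), expr$lineages))
  for (l in expr$lineages)
    out[, l] <- rowMeans(expr$fpkm[, expr$lineage == l, drop = FALSE])
  out
}
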