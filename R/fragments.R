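#' Create a fragment set
#'
#' Fragments are genomic intervals in 0-based half-open coordinates, the raw
#' substrate for all fragmentomic and coverage metrics. Validation enforces
#' `end > start`, non-negative starts, and (when a genome is supplied) known
#' chromosomes with `end` within the chromosome.
#'
#' @param chrom,start,end Vectors of equal length.
#' @param genome Optional [genome_model()] to validate against.
#' @return A data.frame with columns `chrom`, `start`, `end` and class
#'   `fragment_set`.
#' @export
fragment_set <- function(chrom, start, end, genome = NULL) {
  frag <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  validate_fragments(frag, genome)
  class(frag) <- c("fragment_set", "data.frame")
  frag
}

validate_fragments <- function(frag, genome = NULL, line_offset = NULL) {
  where <- function(i) {
    if (is.null(line_offset)) paste0("record ", i) else paste0("line ", i)
  }
  bad <- which(!is.finite(frag$start) | !is.finite(frag$end))
  if (length(bad)) stop_data("non-numeric coordinates at ", where(bad[1]))
  bad <- which(frag$start < 0)
  if (length(bad)) stop_data("negative start coordinate at ", where(bad[1]))
  bad <- which(frag$end <= frag$start)
  if (length(bad)) stop_data("end <= start at ", where(bad[1]))
  if (!is.null(genome)) {
    idx <- match(frag$chrom, genome$chroms$chrom)
    bad <- which(is.na(idx))
    if (length(bad)) {
      stop_data("unknown chromosome '", frag$chrom[bad[1]], "' at ", where(bad[1]))
    }
    bad <- which(frag$end > genome$chroms$length[idx])
    if (length(bad)) stop_data("fragment exceeds chromosome length at ", where(bad[1]))
  }
  invisible(frag)
}

#' Read / write fragment records as 3-column BED
#'
#' `read_fragments()` accepts BED with 3 or more columns (extra columns are
#' ignored) and rejects malformed lines with their line number. An empty
#' file yields an empty fragment set. `write_fragments()` writes
#' tab-separated `chrom start end` with no header; the two functions
#' round-trip exactly.
#'
#' @param path File path.
#' @param genome Optional [genome_model()] to validate chromosomes against.
#' @param frag A [fragment_set()].
#' @return `read_fragments()`: a `fragment_set`.
#' @export
read_fragments <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_config("no such file: ", path)
  if (file.size(path) == 0L) {
    return(fragment_set(character(0), numeric(0), numeric(0), genome))
  }
  raw <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                           colClasses = "character", data.table = FALSE)
  if (ncol(raw) < 3L) stop_data("BED requires at least 3 columns")
  frag <- data.frame(
    chrom = raw[[1]],
    start = suppressWarnings(as.numeric(raw[[2]])),
    end = suppressWarnings(as.numeric(raw[[3]])),
    stringsAsFactors = FALSE
  )
  validate_fragments(frag, genome, line_offset = 0L)
  class(frag) <- c("fragment_set", "data.frame")
  frag
}

#' @rdname read_fragments
#' @export
write_fragments <- function(frag, path) {
  df <- data.frame(frag$chrom,
                   format(frag$start, scientific = FALSE, trim = TRUE),
                   format(frag$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fragment size distribution
#'
#' Tallies fragment lengths (`end - start`) over a stated range; lengths
#' outside the range are not binned but counted as out-of-range.
#'
#' @param frag A [fragment_set()].
#' @param range Closed length range, default `c(10, 500)` bp.
#' @return An object of class `size_distribution` with fields `length`,
#'   `count`, `total` (in-range), and `out_of_range`.
#' @export
size_distribution <- function(frag, range = c(10, 500)) {
  stopifnot(length(range) == 2L, range[1] <= range[2])
  len <- frag$end - frag$start
  lengths <- seq.int(range[1], range[2])
  inr <- len >= range[1] & len <= range[2]
  count <- tabulate(len[inr] - range[1] + 1L, nbins = length(lengths))
  structure(
    list(length = lengths, count = count,
         total = sum(count), out_of_range = sum(!inr)),
    class = "size_distribution"
  )
}

#' @export
print.size_distribution <- function(x, ...) {
  cat("size_distribution:", x$total, "fragments in [", x$length[1], ",",
      x$length[length(x$length)], "] bp;", x$out_of_range, "out of range\n")
  invisible(x)
}

#' Filter fragments by length
#'
#' Retains fragments whose length falls in the closed interval
#' `[lo, hi]` — e.g. the 90–150 bp band used for short-fragment copy-number
#' analysis keeps a 150 bp fragment and drops a 151 bp one.
#'
#' @param frag A [fragment_set()].
#' @param lo,hi Closed length bounds in bp.
#' @return A `fragment_set`.
#' @export
filter_by_length <- function(frag, lo, hi) {
  if (lo > hi) stop_config("lo must not exceed hi")
  len <- frag$end - frag$start
  out <- frag[len >= lo & len <= hi, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Count fragments in genomic bins by length class
#'
#' Each fragment is assigned to the bin containing its midpoint
#' (`floor((start + end) / 2)`), so a fragment spanning a bin boundary is
#' counted exactly once. Length classes are disjoint closed bands (default:
#' short 90–150 bp, long 151–220 bp); fragments outside every band are
#' tallied separately, as are fragments whose midpoint falls past the last
#' full bin of a chromosome.
#'
#' @param frag A [fragment_set()].
#' @param genome A [genome_model()].
#' @param width Bin width in bp.
#' @param length_classes Named list of `c(lo, hi)` closed bands.
#' @return A list with `bins` (data.frame of bin coordinates, covariates and
#'   one count column per class), `out_of_class` and `unbinned` tallies.
#' @export
bin_fragment_counts <- function(frag, genome, width,
                                length_classes = list(short = c(90, 150),
                                                      long = c(151, 220))) {
  stopifnot(length(length_classes) >= 1L)
  bands <- do.call(rbind, lapply(length_classes, function(b) {
    stopifnot(length(b) == 2L, b[1] <= b[2])
    b
  }))
  o <- order(bands[, 1])
  if (any(bands[o, 1][-1] <= bands[o, 2][-nrow(bands)])) {
    stop_config("length classes must be disjoint")
  }
  win <- build_windows(genome, width)
  win <- win[, c("chrom", "start", "end", "arm", "gc", "excluded")]
  n_bins_per_chrom <- table(factor(win$chrom, levels = genome$chroms$chrom))
  offset <- c(0, cumsum(as.numeric(n_bins_per_chrom)))[seq_along(genome$chroms$chrom)]
  names(offset) <- genome$chroms$chrom

  len <- frag$end - frag$start
  mid <- floor((frag$start + frag$end) / 2)
  cls <- rep(NA_integer_, nrow(frag))
  for (k in seq_along(length_classes)) {
    b <- length_classes[[k]]
    cls[len >= b[1] & len <= b[2]] <- k
  }
  out_of_class <- sum(is.na(cls))

  local_bin <- floor(mid / width) + 1L
  max_bin <- as.numeric(n_bins_per_chrom[frag$chrom])
  valid <- !is.na(cls) & local_bin <= max_bin
  unbinned <- sum(!is.na(cls) & local_bin > max_bin)
  global_bin <- offset[frag$chrom] + local_bin

  for (k in seq_along(length_classes)) {
    sel <- valid & cls == k
    win[[names(length_classes)[k]]] <-
      tabulate(global_bin[sel], nbins = nrow(win))
  }
  list(bins = win, out_of_class = out_of_class, unbinned = unbinned)
}
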