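#' Construct a genome model
#'
#' A genome model carries everything the binning and windowing code needs:
#' chromosome names and lengths, the p/q arm split position per chromosome,
#' an optional blacklist of excluded intervals, and deterministic per-window
#' GC and CpG covariate tracks. All coordinates are 0-based, half-open (BED
#' convention).
#'
#' The covariate tracks are synthetic: GC fraction is a smooth sinusoidal
#' landscape plus a positional hash, and CpG counts are a zero-inflated,
#' GC-linked draw, both pure functions of position. This makes
#' [build_windows()] reproducible at any width without storing per-window
#' state.
#'
#' @param chroms Character vector of chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp.
#' @param arm_split Optional numeric vector of p/q boundary positions
#'   (default: half the chromosome length).
#' @param blacklist Optional data.frame with columns `chrom`, `start`, `end`
#'   of intervals to exclude from analysis.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chroms, lengths, arm_split = NULL, blacklist = NULL) {
  if (length(chroms) == 0L) stop_config("genome model needs at least one chromosome")
  if (length(lengths) != length(chroms)) {
    stop_config("chroms and lengths differ in length")
  }
  if (any(lengths <= 0)) stop_config("chromosome lengths must be positive")
  if (is.null(arm_split)) arm_split <- floor(lengths / 2)
  if (any(arm_split < 0 | arm_split > lengths)) {
    stop_config("arm_split must lie within the chromosome")
  }
  if (!is.null(blacklist)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(blacklist)))
    if (!all(blacklist$chrom %in% chroms)) {
      stop_data("blacklist references unknown chromosomes: ",
                paste(setdiff(blacklist$chrom, chroms), collapse = ", "))
    }
    if (any(blacklist$end <= blacklist$start)) {
      stop_data("blacklist intervals must have end > start")
    }
  }
  structure(
    list(
      chroms = data.frame(
        chrom = as.character(chroms),
        length = as.numeric(lengths),
        arm_split = as.numeric(arm_split),
        stringsAsFactors = FALSE
      ),
      blacklist = blacklist
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chroms), "chromosomes,",
      format(sum(x$chroms$length), big.mark = ","), "bp total,",
      if (is.null(x$blacklist)) 0L else nrow(x$blacklist), "blacklist intervals\n")
  invisible(x)
}

genome_chrom_index <- function(genome, chrom) {
  idx <- match(chrom, genome$chroms$chrom)
  if (anyNA(idx)) {
    stop_data("unknown chromosome(s): ",
              paste(unique(chrom[is.na(idx)]), collapse = ", "))
  }
  idx
}

genome_total_length <- function(genome) sum(genome$chroms$length)

# GC fraction at window midpoints: smooth landscape + positional roughness,
# clipped to [0.25, 0.75].
genome_gc_at <- function(genome, chrom, mid) {
  ci <- genome_chrom_index(genome, chrom)
  # the slow landscape shares its phase across chromosomes so GC is
  # identically distributed per chromosome (no chromosome-level GC
  # confound that a loess correction could mistake for copy number)
  gc <- 0.42 +
    0.07 * sin(2 * pi * mid / 1.7e6) +
    0.05 * sin(2 * pi * mid / 2.3e5 + 2 * ci) +
    0.06 * (position_hash(ci, mid, salt = 1) - 0.5)
  pmin(pmax(gc, 0.25), 0.75)
}

# CpG count for a window of the given width: zero-inflated (about 35% of
# windows carry no CpG) with a GC-linked Poisson intensity, scaled to width.
genome_cpg_at <- function(genome, chrom, mid, width) {
  ci <- genome_chrom_index(genome, chrom)
  gc <- genome_gc_at(genome, chrom, mid)
  h_zero <- position_hash(ci, mid, salt = 2)
  h_count <- position_hash(ci, mid, salt = 3)
  lambda <- pmax(0.5, (gc - 0.28) * 28) * (width / 300)
  cpg <- stats::qpois(pmin(h_count, 1 - 1e-12), lambda = lambda)
  cpg[h_zero < 0.35] <- 0L
  as.integer(cpg)
}

#' Tile a genome into fixed-width analysis windows
#'
#' Each chromosome contributes `floor(length / width)` full windows; the
#' trailing partial window is dropped. Windows overlapping a blacklist
#' interval by at least 1 bp are flagged `excluded`.
#'
#' @param genome A [genome_model()].
#' @param width Window width in bp (> 0, no larger than the longest
#'   chromosome).
#' @return A data.frame with columns `chrom`, `start`, `end`, `arm`, `gc`,
#'   `cpg`, `excluded`, in genome order.
#' @export
build_windows <- function(genome, width) {
  if (width <= 0) stop_config("window width must be positive")
  if (width > max(genome$chroms$length)) {
    stop_config("window width exceeds the longest chromosome")
  }
  pieces <- lapply(seq_len(nrow(genome$chroms)), function(i) {
    len <- genome$chroms$length[i]
    n <- floor(len / width)
    if (n == 0L) return(NULL)
    start <- (seq_len(n) - 1) * width
    data.frame(
      chrom = genome$chroms$chrom[i],
      start = start,
      end = start + width,
      stringsAsFactors = FALSE
    )
  })
  win <- do.call(rbind, pieces)
  if (is.null(win)) stop_config("no chromosome can hold a full window")
  mid <- (win$start + win$end) / 2
  split_at <- genome$chroms$arm_split[genome_chrom_index(genome, win$chrom)]
  win$arm <- ifelse(mid < split_at, "p", "q")
  win$gc <- genome_gc_at(genome, win$chrom, mid)
  win$cpg <- genome_cpg_at(genome, win$chrom, mid, width)
  win$excluded <- flag_blacklist(genome, win)
  rownames(win) <- NULL
  win
}

# TRUE for windows overlapping any blacklist interval by >= 1 bp.
flag_blacklist <- function(genome, win) {
  out <- rep(FALSE, nrow(win))
  bl <- genome$blacklist
  if (is.null(bl) || nrow(bl) == 0L) return(out)
  for (ch in unique(bl$chrom)) {
    wi <- which(win$chrom == ch)
    if (!length(wi)) next
    b <- bl[bl$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = win$start[wi] + 1L, end = win$end[wi]),
      IRanges::IRanges(start = b$start + 1L, end = b$end)
    )
    out[wi[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  out
}

# Window id used to key panels and signatures: "chrom:start".
window_id <- function(chrom, start) paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE))
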