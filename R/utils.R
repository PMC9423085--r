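# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stopf("'%s' must be a single number in [%s, %s]", name, min, max)
  invisible(x)
}

#' Derive a reproducible sub-stream seed
#'
#' Stage- and replicate-level seeds are derived deterministically from one
#' global seed so that reordering or toggling pipeline stages does not
#' change the random stream any stage sees. Result is kept below 2^31.
#'
#' @param seed integer global seed.
#' @param offset integer stream offset (stage index, replicate, ...).
#' @return An integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 1000003 + 12345) %%
               2147483647)
}

# GRanges from a 0-based half-open interval data.frame with columns
# chrom/start/end. All internal coordinates are 0-based half-open; IRanges
# is 1-based closed, hence start + 1.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Overlap pairs between two 0-based half-open interval frames.
# Returns data.frame(q_idx, s_idx).
overlap_pairs0 <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(q_idx = integer(0), s_idx = integer(0)))
  hits <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject))
  data.frame(q_idx = S4Vectors::queryHits(hits), s_idx = S4Vectors::subjectHits(hits))
}

# TRUE per query row if it overlaps any subject interval.
overlaps_any0 <- function(query, subject) {
  out <- logical(nrow(query))
  out[unique(overlap_pairs0(query, subject)$q_idx)] <- TRUE
  out
}

# Positions (1-based bp, per chromosome) falling inside 0-based half-open
# intervals: pos p is inside [start, end) iff start < p <= end.
points_in_regions <- function(chrom, pos, regions) {
  if (nrow(regions) == 0L) return(logical(length(pos)))
  pts <- data.frame(chrom = chrom, start = pos - 1L, end = pos)
  overlaps_any0(pts, regions)
}

# Tiling windows over [0, chrom_length), 0-based half-open.
tile_windows <- function(chrom_lengths, window, step = window) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, len))
  })
  do.call(rbind, out)
}

# Chromosome lengths inferred from site positions when not supplied.
infer_chrom_lengths <- function(chrom, pos) {
  tapply(pos, chrom, max)
}
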