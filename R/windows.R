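#' Tile scaffolds into fixed-width windows
#'
#' Windows are 0-based half-open `[start, end)` of constant width (default
#' 2,500 bp, the scan resolution used throughout), except for the terminal
#' window of each scaffold which is truncated at the scaffold length. A site
#' at 1-based position p falls in the window containing p - 1.
#'
#' @param hm a [haplotype_matrix()].
#' @param width window width in bp (> 0).
#' @return data.frame with `scaffold`, `start`, `end` and a running `window`
#'   id; attribute `width` records the tiling width.
#' @export
make_windows <- function(hm, width = 2500) {
  if (width <= 0) stop("width must be > 0")
  width <- as.integer(width)
  scs <- unique(hm$scaffold)
  out <- lapply(scs, function(sc) {
    L <- scaffold_length(hm, sc)
    starts <- seq.int(0L, L - 1L, by = width)
    data.frame(scaffold = sc, start = starts,
               end = pmin(starts + width, L))
  })
  out <- do.call(rbind, out)
  out$window <- seq_len(nrow(out))
  attr(out, "width") <- width
  out
}

#' Assign every site to its window
#'
#' @param hm a [haplotype_matrix()].
#' @param windows a window table from [make_windows()].
#' @return integer vector of window ids, one per site (NA when a site falls
#'   outside the tiled range, which only happens if the window table was
#'   built from a different matrix).
#' @export
assign_windows <- function(hm, windows) {
  idx <- rep(NA_integer_, n_sites(hm))
  for (sc in unique(hm$scaffold)) {
    w <- windows[windows$scaffold == sc, , drop = FALSE]
    if (!nrow(w)) next
    s <- which(hm$scaffold == sc)
    k <- findInterval(hm$positions[s] - 1L, w$start)
    ok <- k >= 1L & (hm$positions[s] - 1L) < w$end[pmax(k, 1L)]
    idx[s[ok]] <- w$window[k[ok]]
  }
  idx
}
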