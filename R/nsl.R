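#' Shared haplotype length (in segregating sites) for one haplotype pair
#'
#' The number of segregating sites spanned by the maximal interval containing
#' the focal site over which the two haplotypes are identical, counted
#' inclusively (both boundary segregating sites of the interval count).
#' Missing alleles truncate the interval like mismatches, and a pair that
#' differs (or is missing) at the focal site itself is undefined (NA).
#'
#' @param hm a [haplotype_matrix()] (a single scaffold; the scan never
#'   crosses scaffold boundaries).
#' @param site focal site index.
#' @param i,j haplotype row indices.
#' @return inclusive segregating-site count, or NA.
#' @export
pairwise_sl <- function(hm, site, i, j) {
  x <- hm$alleles[i, ]
  y <- hm$alleles[j, ]
  if (length(unique(hm$scaffold)) > 1L)
    stop("pairwise_sl expects a single-scaffold matrix")
  brk <- which(x != y | is.na(x) | is.na(y))
  if (site %in% brk) return(NA_real_)
  lo <- brk[brk < site]
  hi <- brk[brk > site]
  a <- if (length(lo)) max(lo) else 0L
  b <- if (length(hi)) min(hi) else length(x) + 1L
  as.numeric(b - a - 1L)
}

# Per-scaffold mean pairwise SL sums for ancestral/derived classes.
# Xd: haplotypes x sites matrix of derived-allele codes (0 ancestral,
# 1 derived, NA missing). Returns per-site sums/counts per class.
sl_class_sums <- function(Xd) {
  H <- nrow(Xd)
  S <- ncol(Xd)
  sumA <- cntA <- sumD <- cntD <- numeric(S)
  for (i in seq_len(H - 1L)) {
    xi <- Xd[i, ]
    for (j in seq(i + 1L, H)) {
      xj <- Xd[j, ]
      brk <- which(xi != xj | is.na(xi) | is.na(xj))
      bounds <- c(0L, brk, S + 1L)
      v <- diff(bounds) - 1L          # sites per identity segment
      keep <- v > 0L
      if (!any(keep)) next
      val <- rep.int(v[keep], v[keep])  # piecewise-constant SL per site
      nonbrk <- if (length(brk)) seq_len(S)[-brk] else seq_len(S)
      isD <- xi[nonbrk] == 1L
      dI <- nonbrk[isD]
      aI <- nonbrk[!isD]
      sumD[dI] <- sumD[dI] + val[isD]
      cntD[dI] <- cntD[dI] + 1
      sumA[aI] <- sumA[aI] + val[!isD]
      cntA[aI] <- cntA[aI] + 1
    }
  }
  list(sumA = sumA, cntA = cntA, sumD = sumD, cntD = cntD)
}

#' Per-site nSL scores for one population
#'
#' nSL contrasts the mean shared-haplotype length among carriers of the
#' derived allele (SL_D) with that among carriers of the ancestral allele
#' (SL_A): raw nSL = ln(SL_A / SL_D). Long derived haplotypes (a sweep)
#' drive nSL negative. Sites are scored only where both allele classes have
#' at least two haplotypes; scaffolds are scanned independently and identity
#' intervals are truncated at scaffold ends and at missing alleles.
#'
#' @param hm a [haplotype_matrix()].
#' @param ancestral ancestral table aligned to `hm` sites (only
#'   `ancestral %in% c("ref","alt")` sites are scored).
#' @param popmap population map.
#' @param population population to scan.
#' @return data.frame per site: `scaffold`, `pos`, `daf` (derived-allele
#'   frequency), `sl_a`, `sl_d`, `nsl` (raw).
#' @export
nsl_scores <- function(hm, ancestral, popmap, population) {
  rows <- population_rows(hm, popmap, pops = population,
                          drop_outgroup = FALSE)[[1L]]
  polarized <- ancestral$ancestral %in% c("ref", "alt")
  out <- data.frame(scaffold = hm$scaffold, pos = hm$positions,
                    daf = NA_real_, sl_a = NA_real_, sl_d = NA_real_,
                    nsl = NA_real_)
  for (sc in unique(hm$scaffold)) {
    sel <- which(hm$scaffold == sc & polarized)
    if (length(sel) < 2L) next
    X <- hm$alleles[rows, sel, drop = FALSE]
    flip <- ancestral$ancestral[sel] == "alt"
    Xd <- X
    if (any(flip)) Xd[, flip] <- 1L - Xd[, flip, drop = FALSE]
    cls <- sl_class_sums(Xd)
    nD <- colSums(Xd == 1L, na.rm = TRUE)
    nA <- colSums(Xd == 0L, na.rm = TRUE)
    n_obs <- nD + nA
    sl_a <- ifelse(cls$cntA > 0, cls$sumA / cls$cntA, NA_real_)
    sl_d <- ifelse(cls$cntD > 0, cls$sumD / cls$cntD, NA_real_)
    ok <- nA >= 2L & nD >= 2L
    nsl <- ifelse(ok & sl_a > 0 & sl_d > 0, log(sl_a / sl_d), NA_real_)
    out$daf[sel] <- nD / n_obs
    out$sl_a[sel] <- ifelse(ok, sl_a, NA_real_)
    out$sl_d[sel] <- ifelse(ok, sl_d, NA_real_)
    out$nsl[sel] <- nsl
  }
  out
}

#' Standardize nSL within derived-frequency bins
#'
#' Raw nSL depends on the derived-allele frequency, so scores are centred
#' and scaled within frequency bins (default width 0.02). Bins with fewer
#' than `min_bin` scored sites are merged with their neighbours before
#' standardizing; a bin with zero variance gets missing scores with a
#' warning.
#'
#' @param scores output of [nsl_scores()].
#' @param bin_width derived-frequency bin width.
#' @param min_bin minimum scored sites per bin.
#' @return `scores` with `bin` and `nsl_std` columns added.
#' @export
standardize_nsl <- function(scores, bin_width = 0.02, min_bin = 50) {
  ok <- which(!is.na(scores$nsl))
  edges <- seq(0, 1, by = bin_width)
  bin <- findInterval(scores$daf[ok], edges, rightmost.closed = TRUE)
  # merge under-filled bins into their left neighbour (cascading)
  tab <- table(bin)
  lab <- sort(unique(bin))
  merged <- stats::setNames(lab, lab)
  counts <- as.numeric(tab[as.character(lab)])
  i <- 1L
  while (i <= length(lab)) {
    if (counts[i] < min_bin && length(lab) > 1L) {
      j <- if (i > 1L) i - 1L else i + 1L
      counts[j] <- counts[j] + counts[i]
      merged[merged == lab[i]] <- lab[j]
      lab <- lab[-i]
      counts <- counts[-i]
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  bin <- as.integer(merged[as.character(bin)])
  z <- rep(NA_real_, length(ok))
  for (b in unique(bin)) {
    idx <- bin == b
    v <- scores$nsl[ok][idx]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      warning("zero-variance nSL bin; scores set missing")
      next
    }
    z[idx] <- (v - mean(v)) / s
  }
  scores$bin <- NA_integer_
  scores$bin[ok] <- bin
  scores$nsl_std <- NA_real_
  scores$nsl_std[ok] <- z
  scores
}

#' Summarize standardized nSL into windows
#'
#' Window statistic is the maximum |standardized nSL| in the window
#' (preserves localized sweep signals; `reduce = "mean"` is available).
#' Empty windows are missing.
#'
#' @param scores output of [standardize_nsl()].
#' @param windows window table from [make_windows()].
#' @param reduce `"max_abs"` or `"mean"`.
#' @return numeric vector, one statistic per window.
#' @export
window_summarize_nsl <- function(scores, windows, reduce = c("max_abs", "mean")) {
  reduce <- match.arg(reduce)
  hm_like <- list(positions = scores$pos, scaffold = scores$scaffold)
  widx <- rep(NA_integer_, nrow(scores))
  for (sc in unique(scores$scaffold)) {
    w <- windows[windows$scaffold == sc, , drop = FALSE]
    if (!nrow(w)) next
    s <- which(scores$scaffold == sc)
    k <- findInterval(scores$pos[s] - 1L, w$start)
    okk <- k >= 1L & (scores$pos[s] - 1L) < w$end[pmax(k, 1L)]
    widx[s[okk]] <- w$window[k[okk]]
  }
  out <- rep(NA_real_, nrow(windows))
  ok <- !is.na(widx) & !is.na(scores$nsl_std)
  if (!any(ok)) return(out)
  f <- if (reduce == "max_abs") function(v) max(abs(v)) else mean
  agg <- tapply(scores$nsl_std[ok], widx[ok], f)
  out[as.integer(names(agg))] <- agg
  out
}
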