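#' Discard low-rate units
#'
#' Units with an overall firing rate strictly below `min_rate` (default
#' 0.3 spikes/s) are removed before any cross-correlogram analysis; a unit
#' at exactly the minimum rate is kept.
#'
#' @param trains Named list of spike-time vectors (s).
#' @param duration_s Recording duration (s).
#' @param min_rate Minimum rate in spikes/s (default 0.3).
#' @return The filtered list.
#' @export
rate_filter <- function(trains, duration_s, min_rate = 0.3) {
  stopifnot(duration_s > 0)
  rates <- vapply(trains, length, numeric(1)) / duration_s
  trains[rates >= min_rate]
}

#' Cross-correlogram between two spike trains
#'
#' Counts of post-synaptic spikes at each lag relative to every
#' pre-synaptic spike, in centered bins (bin centered at lag `c` ms covers
#' `[c - bin/2, c + bin/2)`), unsmoothed, zero-lag bin included.
#'
#' @param pre,post Numeric vectors of spike times (s), non-empty.
#' @param bin_ms Bin width in ms (default 1).
#' @param window_ms Half-width of the lag window in ms (default 50).
#' @return List of class `so_ccg` with `lags_ms` (bin centers), `counts`,
#'   `bin_ms`, `n_pre`, `n_post`.
#' @export
compute_ccg <- function(pre, post, bin_ms = 1, window_ms = 50) {
  if (!length(pre) || !length(post)) stop("empty spike train")
  pre <- sort(pre)
  post <- sort(post)
  centers <- seq(-window_ms, window_ms, by = bin_ms)
  edges_s <- (c(centers - bin_ms / 2, centers[length(centers)] + bin_ms / 2)) /
    1000
  # counts of post spikes with lag < e, summed over pre spikes, per edge
  cum <- vapply(edges_s, function(e) {
    sum(findInterval(pre + e, post))
  }, numeric(1))
  structure(list(lags_ms = centers, counts = diff(cum), bin_ms = bin_ms,
                 n_pre = length(pre), n_post = length(post)),
            class = "so_ccg")
}

#' @export
print.so_ccg <- function(x, ...) {
  cat(sprintf("<so_ccg> %d bins of %g ms, lags %g..%g ms, %d pairs counted\n",
              length(x$counts), x$bin_ms, min(x$lags_ms), max(x$lags_ms),
              sum(x$counts)))
  invisible(x)
}

#' Cross-correlogram deficit score
#'
#' Default inhibition-strength screen: the relative deficit of the mean
#' cross-correlogram count inside a post-lag scoring window versus the mean
#' over the whole correlogram, `1 - mean(x[window]) / mean(x)`. Positive for
#' a trough (putative inhibition), near zero for independent trains. Any
#' function with the same signature can be substituted as the screening
#' scorer.
#'
#' @param ccg An `so_ccg`.
#' @param score_window_ms Two-element lag window in ms (default `c(4, 9)`).
#' @return Unitless scalar score.
#' @export
ccg_deficit_score <- function(ccg, score_window_ms = c(4, 9)) {
  m <- mean(ccg$counts)
  if (m <= 0) return(0)
  sel <- ccg$lags_ms >= score_window_ms[1] & ccg$lags_ms <= score_window_ms[2]
  1 - mean(ccg$counts[sel]) / m
}

#' Screen ordered unit pairs for candidate inhibitory connections
#'
#' Computes the cross-correlogram of every ordered pair of rate-filtered
#' units, scores each with the screening scorer (default
#' [ccg_deficit_score()]), and retains, per pre-synaptic unit, the `top_n`
#' highest-scoring pairs for classification by [classify_inhibitory()].
#'
#' @param trains Named list of spike-time vectors (already rate-filtered).
#' @param top_n Connections retained per pre-synaptic unit (default 20).
#' @param bin_ms,window_ms Cross-correlogram parameters.
#' @param scorer Function `(ccg) -> numeric` used for ranking.
#' @param classify Logical: also run [classify_inhibitory()] on the retained
#'   candidates (default TRUE).
#' @param ... Passed to [classify_inhibitory()].
#' @return Data frame with `pre`, `post`, `screen_score`, and (when
#'   `classify`) `is_inhibitory`; the correlograms are attached as the
#'   `ccgs` attribute (named `"pre->post"`).
#' @export
screen_connections <- function(trains, top_n = 20, bin_ms = 1, window_ms = 50,
                               scorer = ccg_deficit_score, classify = TRUE,
                               ...) {
  ids <- names(trains)
  if (is.null(ids)) ids <- as.character(seq_along(trains))
  if (length(trains) < 2) stop("need at least two units after rate filtering")
  rows <- list()
  ccgs <- list()
  for (i in seq_along(trains)) {
    for (j in seq_along(trains)) {
      if (i == j) next
      cc <- compute_ccg(trains[[i]], trains[[j]], bin_ms, window_ms)
      key <- paste0(ids[i], "->", ids[j])
      ccgs[[key]] <- cc
      rows[[key]] <- data.frame(pre = ids[i], post = ids[j],
                                screen_score = scorer(cc),
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # per pre-synaptic unit, keep the top_n highest scores
  keep <- unlist(lapply(split(seq_len(nrow(out)), out$pre), function(ix) {
    ix[order(out$screen_score[ix], decreasing = TRUE)[seq_len(min(top_n,
                                                                  length(ix)))]]
  }), use.names = FALSE)
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  if (classify) {
    res <- lapply(paste0(out$pre, "->", out$post), function(k)
      classify_inhibitory(ccgs[[k]], ...))
    out$is_inhibitory <- vapply(res, `[[`, logical(1), "is_inhibitory")
  }
  attr(out, "ccgs") <- ccgs[paste0(out$pre, "->", out$post)]
  out
}

#' Classify a candidate connection as inhibitory
#'
#' A connection is inhibitory when the cross-correlogram counts `x` fall
#' below `mean(x) - sd(x)` in at least `min_consecutive` (default 4)
#' consecutive 1 ms bins inside the 4-9 ms post-lag window. Mean and SD are
#' taken over the full correlogram. A degenerate correlogram (`sd = 0`) is
#' never inhibitory and is flagged.
#'
#' @param ccg An `so_ccg` spanning at least the test window.
#' @param test_window_ms Lag window whose bins are tested (default
#'   `c(4, 9)`, i.e. the six bins centered at 4..9 ms at 1 ms binning).
#' @param min_consecutive Minimum run of deficient bins (default 4).
#' @return List with `is_inhibitory`, `qualifying_lags_ms` (bins in the
#'   longest deficient run, empty when not inhibitory), and `degenerate`.
#' @export
classify_inhibitory <- function(ccg, test_window_ms = c(4, 9),
                                min_consecutive = 4) {
  stopifnot(inherits(ccg, "so_ccg"))
  if (max(ccg$lags_ms) < test_window_ms[2])
    stop("correlogram does not span the test window")
  x <- ccg$counts
  mu <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    return(list(is_inhibitory = FALSE, qualifying_lags_ms = numeric(0),
                degenerate = TRUE))
  sel <- which(ccg$lags_ms >= test_window_ms[1] &
                 ccg$lags_ms <= test_window_ms[2])
  deficient <- x[sel] < mu - s
  r <- rle(deficient)
  best <- 0L
  pos <- 0L
  end <- cumsum(r$lengths)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] > best) {
      best <- r$lengths[k]
      pos <- end[k] - r$lengths[k] + 1L
    }
  }
  hit <- best >= min_consecutive
  list(is_inhibitory = hit,
       qualifying_lags_ms = if (hit) ccg$lags_ms[sel[pos:(pos + best - 1L)]]
       else numeric(0),
       degenerate = FALSE)
}
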