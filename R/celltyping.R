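CELLTYPE_FEATURES <- c("r_in", "delta_ahp", "sag", "rheobase", "spike_width",
                       "rp")

# stated seeding geometry for the three clusters in PCA space: putative Exc
# on the positive first axis, FS and LTS on the negative side split by the
# second axis
DEFAULT_CENTROIDS <- matrix(c(5, 0, -15, -15, -15, 10), ncol = 2,
                            byrow = TRUE,
                            dimnames = list(c("c1", "c2", "c3"),
                                            c("x", "y")))

#' Extract intrinsic electrophysiological features from current steps
#'
#' Computes the six features used for cell typing from a set of
#' current-step voltage responses: input resistance (`r_in`, MOhm) from the
#' steady-state deflection of the hyperpolarizing step; `sag` (unitless,
#' `(peak - steady state)/peak` deflection on the same step); `rheobase`
#' (pA), the smallest step current eliciting at least one spike;
#' `spike_width` (ms) at half amplitude of the first spike at rheobase;
#' `delta_ahp` (mV), the depth of the after-hyperpolarization below spike
#' threshold; and resting potential `rp` (mV) from the pre-step baseline.
#'
#' @param steps List of steps; each element a list with `current_pA` and
#'   `vm` (an `so_ts` voltage trace), plus `step_window_s`
#'   (`c(on_s, off_s)` of the current step within the trace).
#' @param spike_peak_mv Voltage criterion for spike detection (default 0).
#' @param dvdt_thresh Spike-threshold criterion in mV/ms (default 20).
#' @return Named list with the six features. Errors if no depolarizing step
#'   elicits a spike (rheobase undefined; cell excluded).
#' @export
extract_features <- function(steps, spike_peak_mv = 0, dvdt_thresh = 20) {
  cur <- vapply(steps, `[[`, numeric(1), "current_pA")
  if (!any(cur < 0) || !any(cur > 0))
    stop("need at least one hyperpolarizing and one depolarizing step")

  step_vm <- function(st) {
    vm <- st$vm
    tm <- ts_time(vm)
    on <- st$step_window_s[1]
    off <- st$step_window_s[2]
    list(pre = as.numeric(vm)[tm < on],
         dur = as.numeric(vm)[tm >= on & tm < off],
         post = as.numeric(vm)[tm >= off],
         fs = ts_fs(vm))
  }

  # resting potential: pre-step baseline, averaged across steps
  rp <- mean(vapply(steps, function(st) mean(step_vm(st)$pre), numeric(1)))

  # hyperpolarizing step: use the most negative current
  hyp <- steps[[which.min(cur)]]
  hv <- step_vm(hyp)
  base <- mean(hv$pre)
  # steady state from the last 10% of the step
  nss <- max(1L, round(length(hv$dur) * 0.1))
  v_ss <- mean(hv$dur[(length(hv$dur) - nss + 1):length(hv$dur)])
  v_pk <- min(hv$dur)
  defl_ss <- base - v_ss
  defl_pk <- base - v_pk
  r_in <- defl_ss / (abs(min(cur)) / 1000)  # mV / nA = MOhm
  sag <- if (defl_pk > 0) (defl_pk - defl_ss) / defl_pk else 0

  # rheobase: smallest depolarizing current with >= 1 spike
  dep <- order(cur)
  dep <- dep[cur[dep] > 0]
  rheo_idx <- NA_integer_
  for (i in dep) {
    if (any(as.numeric(steps[[i]]$vm) >= spike_peak_mv)) {
      rheo_idx <- i
      break
    }
  }
  if (is.na(rheo_idx))
    stop("no depolarizing step elicited a spike: rheobase undefined")
  rheobase <- cur[rheo_idx]

  sp <- first_spike_features(steps[[rheo_idx]]$vm, spike_peak_mv, dvdt_thresh)

  list(r_in = r_in, delta_ahp = sp$delta_ahp, sag = sag, rheobase = rheobase,
       spike_width = sp$width_ms, rp = rp)
}

# width at half amplitude and AHP depth of the first spike in a trace
first_spike_features <- function(vm, spike_peak_mv, dvdt_thresh) {
  v <- as.numeric(vm)
  fs <- ts_fs(vm)
  above <- which(v >= spike_peak_mv)
  pk_start <- above[1]
  # spike peak: local max of the first suprathreshold excursion
  run_end <- pk_start
  while (run_end < length(v) && v[run_end + 1] >= spike_peak_mv)
    run_end <- run_end + 1
  pk <- pk_start - 1 + which.max(v[pk_start:run_end])
  # threshold: detect the upstroke where dV/dt crosses the criterion, then
  # walk back to where the trace is locally flat (dV/dt < 5% of the
  # criterion) so the threshold voltage is read at spike onset
  dvdt <- c(0, diff(v)) * fs / 1000  # mV per ms
  pre <- which(dvdt[seq_len(pk)] >= dvdt_thresh)
  thr_idx <- if (length(pre)) pre[1] - 1L else pk - 1L
  while (thr_idx > 1L && dvdt[thr_idx] >= 0.05 * dvdt_thresh)
    thr_idx <- thr_idx - 1L
  thr_idx <- max(thr_idx, 1L)
  v_thr <- v[thr_idx]
  half <- v_thr + (v[pk] - v_thr) / 2
  # half-amplitude crossings by linear interpolation around the peak
  i_up <- thr_idx - 1 + which(v[thr_idx:pk] >= half)[1]
  t_up <- interp_cross(v, i_up - 1L, half)
  after <- pk - 1L + which(v[pk:length(v)] <= half)
  if (!length(after)) stop("spike does not repolarize within the trace")
  i_dn <- after[1]
  t_dn <- interp_cross(v, i_dn - 1L, half)
  width_ms <- (t_dn - t_up) / fs * 1000
  # AHP: minimum in the 30 ms following the spike, referenced to threshold
  # (bounded so the step-offset relaxation is not mistaken for the AHP)
  i_end <- min(length(v), i_dn + round(0.03 * fs))
  delta_ahp <- v_thr - min(v[i_dn:i_end])
  list(width_ms = width_ms, delta_ahp = delta_ahp)
}

# fractional sample position where v crosses `level` between i and i+1
interp_cross <- function(v, i, level) {
  i <- max(i, 1L)
  if (v[i + 1] == v[i]) return(i)
  i + (level - v[i]) / (v[i + 1] - v[i])
}

#' Fit the PCA + Gaussian-mixture cell-typing model
#'
#' Standardizes the six intrinsic features, projects onto the first two
#' principal components, and fits a three-component Gaussian mixture with
#' diagonal, component-specific covariances by expectation-maximization.
#' The mixture is initialized from a k-means partition seeded at the three
#' stated centroid positions (5, 0), (-15, -15), (-15, 10); because those
#' coordinates presuppose a feature scaling that is not reproducible, the
#' seed geometry is affinely rescaled onto the span of the projected data
#' before use. Components are mapped to labels by their mean feature
#' signatures: `Exc` has the widest spikes, and among the remaining two,
#' `FS` has the higher rheobase and lower input resistance, `LTS` the
#' converse.
#'
#' @param features Data frame with columns `r_in`, `delta_ahp`, `sag`,
#'   `rheobase`, `spike_width`, `rp` (one row per cell).
#' @param centroids 3x2 matrix of k-means seeds in PCA coordinates.
#' @param posterior_threshold Minimum posterior for assignment (default 0.9).
#' @param em_tol,em_itmax EM convergence controls.
#' @return List of class `so_celltype_model` with scaling parameters, PCA
#'   loadings, mixture parameters, and the component-to-label map.
#' @export
fit_celltype_model <- function(features, centroids = DEFAULT_CENTROIDS,
                               posterior_threshold = 0.9,
                               em_tol = 1e-6, em_itmax = 500) {
  stopifnot(all(CELLTYPE_FEATURES %in% names(features)))
  X <- as.matrix(features[, CELLTYPE_FEATURES])
  if (nrow(X) < 9) stop("need at least 9 cells (3 per cluster) to fit")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- pca$x[, 1:2, drop = FALSE]

  km <- seeded_kmeans(scores, centroids)
  z0 <- mclust::unmap(km, groups = 1:3)
  fit <- mclust::meVVI(data = scores, z = z0,
                       control = mclust::emControl(tol = em_tol,
                                                   itmax = em_itmax))
  if (is.null(fit$parameters) || any(!is.finite(fit$parameters$pro)) ||
      any(fit$parameters$pro < 1e-8) || anyNA(fit$parameters$mean))
    stop("degenerate mixture fit (empty component); fit rejected")
  # a cohort without three-cluster structure (e.g. a single class) is
  # degenerate: reject the fit when one diagonal Gaussian explains the
  # projected data at least as well by BIC as the three-component mixture
  n <- nrow(scores)
  ll1 <- sum(vapply(1:2, function(j) {
    mu <- mean(scores[, j])
    s <- sqrt(mean((scores[, j] - mu)^2))
    sum(stats::dnorm(scores[, j], mu, s, log = TRUE))
  }, numeric(1)))
  bic3 <- -2 * fit$loglik + 14 * log(n)  # 2 weights + 6 means + 6 variances
  bic1 <- -2 * ll1 + 4 * log(n)
  if (bic1 <= bic3)
    stop("degenerate mixture fit: no three-cluster structure in the data")

  label_map <- map_components(fit$z, X)
  structure(list(center = ctr, scale = scl,
                 loadings = pca$rotation[, 1:2, drop = FALSE],
                 parameters = fit$parameters, label_map = label_map,
                 posterior_threshold = posterior_threshold),
            class = "so_celltype_model")
}

# k-means seeded at the stated centroid geometry, rescaled to the data span;
# falls back to deterministic maximin seeds if a seed captures no points
seeded_kmeans <- function(scores, centroids) {
  sc <- centroids
  for (d in 1:2) {
    rng_d <- range(scores[, d])
    rng_c <- range(centroids[, d])
    span_c <- diff(rng_c)
    if (span_c > 0) {
      sc[, d] <- (centroids[, d] - mean(rng_c)) / span_c * diff(rng_d) +
        mean(rng_d)
    } else {
      sc[, d] <- mean(rng_d)
    }
  }
  km <- tryCatch(
    stats::kmeans(scores, centers = sc, iter.max = 100,
                  algorithm = "Lloyd")$cluster,
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(km) && length(unique(km)) == 3) return(km)
  # maximin fallback: farthest point from the centroid, then the two points
  # successively farthest from all chosen seeds (deterministic)
  d0 <- rowSums(sweep(scores, 2, colMeans(scores))^2)
  seeds <- which.max(d0)
  for (k in 2:3) {
    dmin <- apply(scores, 1, function(p)
      min(colSums((t(scores[seeds, , drop = FALSE]) - p)^2)))
    seeds <- c(seeds, which.max(dmin))
  }
  stats::kmeans(scores, centers = scores[seeds, , drop = FALSE],
                iter.max = 100, algorithm = "Lloyd")$cluster
}

# map mixture components to Exc/FS/LTS by mean feature signatures
map_components <- function(z, X) {
  hard <- max.col(z)
  mean_feat <- function(g, f) mean(X[hard == g, f])
  comps <- 1:3
  sw <- vapply(comps, mean_feat, numeric(1), f = "spike_width")
  exc <- comps[which.max(sw)]
  rest <- setdiff(comps, exc)
  # FS: high rheobase, low input resistance (z-scored contrast)
  zs <- function(f) {
    v <- vapply(rest, mean_feat, numeric(1), f = f)
    if (stats::sd(v) == 0) return(c(0, 0))
    (v - mean(v)) / stats::sd(v)
  }
  fs_score <- zs("rheobase") - zs("r_in")
  fs <- rest[which.max(fs_score)]
  lts <- setdiff(rest, fs)
  map <- character(3)
  map[exc] <- "Exc"
  map[fs] <- "FS"
  map[lts] <- "LTS"
  map
}

#' Assign cell types by posterior probability (soft clustering)
#'
#' Projects each cell into the model's PCA space, computes posterior
#' probabilities under the fitted mixture, and labels by the maximum
#' posterior when it reaches the threshold (default 90%); cells below the
#' threshold are `"unassigned"` and are intended to be discarded from
#' further analysis.
#'
#' @param model A fitted [fit_celltype_model()].
#' @param features Data frame of cells to assign (six feature columns).
#' @return Data frame with `label` and posterior columns `p_Exc`, `p_FS`,
#'   `p_LTS`.
#' @export
assign_celltype <- function(model, features) {
  stopifnot(inherits(model, "so_celltype_model"))
  X <- as.matrix(features[, CELLTYPE_FEATURES])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  scores <- Z %*% model$loadings
  es <- mclust::estepVVI(data = scores, parameters = model$parameters)
  z <- es$z
  lab <- vapply(seq_len(nrow(z)), function(i) {
    if (max(z[i, ]) >= model$posterior_threshold)
      model$label_map[which.max(z[i, ])]
    else "unassigned"
  }, character(1))
  post <- matrix(NA_real_, nrow(z), 3,
                 dimnames = list(NULL, paste0("p_", c("Exc", "FS", "LTS"))))
  for (k in 1:3) post[, paste0("p_", model$label_map[k])] <- z[, k]
  out <- data.frame(label = lab, post, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
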