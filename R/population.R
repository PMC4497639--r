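## Population factory: single-parameter model sweeps for the coding-space
## sensitivity analysis, and a synthetic reference population standing in for
## a recorded DIN sample (which is not publicly available). The reference
## population is labelled "synthetic" throughout: it reproduces the
## qualitative group structure (tight ON and OFF clusters traversed by the
## sweeps, dispersed SP/DP groups, an unspecific group near the origin), not
## any recorded neuron.

#' Build the single-parameter model sweep population
#'
#' The sweep population varies exactly one parameter per model variant:
#' * **ON**: offsets -0.2 (reference), -0.1, 0, 0.05 and 0.01 — increasing
#'   background drive, decreasing movement selectivity.
#' * **OFF**: normalization 40 divided by 0.1, 0.4, 0.7 and 1.3 — the
#'   smallest value, 40/1.3 = 30.77, is the most movement-sensitive and is
#'   still 1.5 times the ON normalization of 20.
#' * **SP** and **DP** (dorsal): the Wd:Wv weight proportion varied over
#'   1:0, 1:0.2, 1:0.4, 1:0.6 and 1:0.8 — decreasing posture selectivity.
#'
#' plus one input-free `RANDOM` neuron. The dynamic extreme
#' position-sensitive variant is excluded (the selectivity scores cannot
#' distinguish it from other dynamic position-sensitive neurons), so the
#' sweep holds 5 + 4 + 5 + 5 = 19 pathway-driven neurons plus the random one.
#'
#' @return an object of class `population_spec`: data frame `neurons`
#'   (`id`, `group`, `sweep_param`, `sweep_value`) with a list-column-free
#'   parallel list `params` of [din_params()].
#' @export
build_sweep_population <- function() {
  entries <- list()
  on_offsets <- c(-0.2, -0.1, 0, 0.05, 0.01)
  for (i in seq_along(on_offsets)) {
    p <- din_preset("ON"); p$offset <- on_offsets[i]
    entries[[length(entries) + 1L]] <-
      list(group = "ON", sweep_param = "offset",
           sweep_value = on_offsets[i], params = p)
  }
  off_divisors <- c(0.1, 0.4, 0.7, 1.3)
  for (d in off_divisors) {
    p <- din_preset("OFF"); p$norm <- 40 / d
    entries[[length(entries) + 1L]] <-
      list(group = "OFF", sweep_param = "norm", sweep_value = 40 / d,
           params = p)
  }
  wv_ratio <- c(0, 0.2, 0.4, 0.6, 0.8)
  for (w in wv_ratio) {
    p <- din_preset("SP_d"); p$wv <- w
    entries[[length(entries) + 1L]] <-
      list(group = "SP", sweep_param = "wv", sweep_value = w, params = p)
    q <- din_preset("DP_d"); q$wv <- w
    entries[[length(entries) + 1L]] <-
      list(group = "DP", sweep_param = "wv", sweep_value = w, params = q)
  }
  entries[[length(entries) + 1L]] <-
    list(group = "RANDOM", sweep_param = "none", sweep_value = NA_real_,
         params = din_preset("RANDOM"))
  new_population_spec(entries, kind = "sweep")
}

new_population_spec <- function(entries, kind) {
  neurons <- data.frame(
    id = seq_along(entries),
    group = vapply(entries, `[[`, character(1), "group"),
    sweep_param = vapply(entries, `[[`, character(1), "sweep_param"),
    sweep_value = vapply(entries, `[[`, numeric(1), "sweep_value")
  )
  structure(list(neurons = neurons,
                 params = lapply(entries, `[[`, "params"),
                 kind = kind),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s population, %d neurons\n",
              x$kind, nrow(x$neurons)))
  print(table(x$neurons$group))
  invisible(x)
}

#' Build a synthetic reference population
#'
#' Generates a labelled stand-in for a recorded DIN sample with five groups
#' (SP, DP, ON, OFF, UN). Each neuron of the four modelled groups draws its
#' group-defining parameter uniformly over the range the corresponding
#' single-parameter sweep traverses, reproducing the spread of a real
#' population that those sweeps were designed to cover; a secondary
#' multiplicative jitter (default 10%) perturbs the normalization. SP and DP
#' neurons come in exact dorsal/ventral mirror pairs with stratified
#' cross-talk weight ratios (see the source comments), so the signed
#' position axis is exactly balanced and evenly covered. The UN
#' ("unspecific") group consists of input-free constant-activation neurons
#' with jittered rates, mirroring a movement-indifferent background group.
#'
#' The default group sizes (SP 8, DP 8, ON 32, OFF 28, UN 12; 88 neurons)
#' weight the movement-sensitive groups
#' more heavily, which reproduces the documented structure of the recorded
#' coding-space: a motion-dominated first principal component, a
#' position-dominated second, and near-equal variance shares whose order can
#' swap under resampling. See the methods vignette.
#'
#' @param n_per_group neurons per group: a named vector over
#'   `SP, DP, ON, OFF, UN`, or a single count applied to every group.
#' @param jitter multiplicative half-width of the secondary jitter on the
#'   normalization (default 0.1; 0 disables all jitter so every neuron equals
#'   its group's reference parameterization — the per-side preset for SP/DP,
#'   with sweep parameters at mid-range).
#' @param seed integer seed.
#' @return a `population_spec` (kind `"reference"`).
#' @export
build_reference_population <- function(n_per_group = c(SP = 8, DP = 8,
                                                       ON = 32, OFF = 28,
                                                       UN = 12),
                                       jitter = 0.1, seed = 1L) {
  groups <- c("SP", "DP", "ON", "OFF", "UN")
  if (length(n_per_group) == 1L && is.null(names(n_per_group)))
    n_per_group <- stats::setNames(rep(n_per_group, 5), groups)
  stopifnot(all(groups %in% names(n_per_group)), all(n_per_group >= 1),
            jitter >= 0)
  entries <- list()
  jit <- function(s) if (jitter == 0) 1 else
    with_seed(s, stats::runif(1, 1 - jitter, 1 + jitter))
  unif <- function(s, lo, hi) if (jitter == 0) (lo + hi) / 2 else
    with_seed(s, stats::runif(1, lo, hi))
  pick <- function(i, a, b) if (i %% 2 == 1L) a else b
  add <- function(group, params) {
    entries[[length(entries) + 1L]] <<-
      list(group = group, sweep_param = "reference",
           sweep_value = NA_real_, params = params)
  }
  for (i in seq_len(n_per_group[["ON"]])) {
    # ON: offset over the sweep range [-0.2, 0.05], dilated 10%
    p <- din_preset("ON")
    p$offset <- unif(derive_seed(seed, 1, i), -0.225, 0.075)
    p$norm <- p$norm * jit(derive_seed(seed, 1, i, 2))
    add("ON", p)
  }
  for (i in seq_len(n_per_group[["OFF"]])) {
    # OFF: norm over the sweep range [40/1.3, 40/0.1], dilated 10%
    p <- din_preset("OFF")
    p$norm <- 40 / unif(derive_seed(seed, 2, i), 0.09, 1.43)
    add("OFF", p)
  }
  # SP/DP cross-talk weight ratios are stratified over the interior of the
  # sweep range (midpoints of npairs equal bins of [0, 0.8]) rather than
  # drawn at random, and neurons come in exact dorsal/ventral mirror pairs
  # (same ratio and jitter, sides swapped). The stratification guarantees
  # even coverage of the posture axis at any group size, and the bilateral
  # symmetry zeroes the sample covariance between the signed position block
  # and the motion block, keeping the principal axes from tilting into each
  # other.
  strat_w <- function(npairs) (seq_len(npairs) - 0.5) / npairs * 0.8
  sp_w <- strat_w(max(1L, n_per_group[["SP"]] %/% 2L))
  for (i in seq_len(n_per_group[["SP"]])) {
    p <- din_preset(pick(i, "SP_d", "SP_v"))
    w <- sp_w[(i + 1L) %/% 2L]
    if (p$wd == 1) p$wv <- w else p$wd <- w
    p$norm <- p$norm * jit(derive_seed(seed, 3, (i + 1L) %/% 2L, 3))
    add("SP", p)
  }
  dp_w <- strat_w(max(1L, n_per_group[["DP"]] %/% 2L))
  for (i in seq_len(n_per_group[["DP"]])) {
    p <- din_preset(pick(i, "DP_d", "DP_v"))
    w <- dp_w[(i + 1L) %/% 2L]
    if (p$wd == 1) p$wv <- w else p$wd <- w
    p$norm <- p$norm * jit(derive_seed(seed, 4, (i + 1L) %/% 2L, 3))
    add("DP", p)
  }
  for (i in seq_len(n_per_group[["UN"]])) {
    # UN: input-free constant-activation neuron, rate ~ U(10, 40) Hz
    p <- din_preset("RANDOM")
    p$label <- "UN"
    p$const_act <- unif(derive_seed(seed, 5, i), 0.10, 0.40)
    add("UN", p)
  }
  new_population_spec(entries, kind = "reference")
}

#' Run a population through the full pathway
#'
#' Characterizes every neuron of a `population_spec` with
#' [characterize_neuron()] (staircases at the four analysis velocities,
#' `n_trials` trials each, fresh afferent noise per neuron and trial) and
#' returns the neurons x 12 selectivity matrix with group labels.
#'
#' @param spec a `population_spec`.
#' @param velocities four analysis velocities (degrees/s).
#' @param n_trials trials per velocity (default 4).
#' @param afferents an [afferent_params()].
#' @param hold_duration staircase hold duration (s).
#' @param seed master seed; neuron i uses `derive_seed(seed, i)`.
#' @return list with `scores` (matrix), `labels` (character), `spec`.
#' @export
run_population <- function(spec, velocities = c(12, 50, 150, 400),
                           n_trials = 4, afferents = afferent_params(),
                           hold_duration = 1, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  n <- nrow(spec$neurons)
  scores <- matrix(NA_real_, n, 12,
                   dimnames = list(NULL, score_colnames()))
  for (i in seq_len(n)) {
    sv <- characterize_neuron(din_simulator(spec$params[[i]], afferents),
                              velocities = velocities, n_trials = n_trials,
                              hold_duration = hold_duration,
                              dt = afferents$dt,
                              seed = derive_seed(seed, i))
    scores[i, ] <- as.numeric(sv)
  }
  list(scores = scores, labels = spec$neurons$group, spec = spec)
}

#' Export a labelled selectivity matrix as CSV
#'
#' Columns: `neuron_id`, `group`, then the 12 score columns.
#' @param result a list with `scores` and `labels` (from [run_population()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_selectivity_csv <- function(result, path) {
  df <- data.frame(neuron_id = seq_len(nrow(result$scores)),
                   group = result$labels, result$scores,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convex-hull containment with margin
#'
#' Tests whether points fall inside the convex hull of a reference point set,
#' dilated by `margin`: a point passes if it is inside the hull or within
#' `margin` of its boundary. Used to check that swept model neurons land in
#' the coding-space region occupied by their reference group.
#'
#' @param px,py coordinates of the test points.
#' @param rx,ry coordinates of the reference set (>= 3 points).
#' @param margin dilation distance (same units as the coordinates).
#' @return logical vector, one per test point.
#' @export
in_dilated_hull <- function(px, py, rx, ry, margin = 0.25) {
  stopifnot(length(rx) >= 3L, length(rx) == length(ry))
  h <- grDevices::chull(rx, ry)
  hx <- rx[h]; hy <- ry[h]
  k <- length(h)
  vapply(seq_along(px), function(i) {
    dist_to_hull(px[i], py[i], hx, hy, k) <= margin
  }, logical(1))
}

## signed-ish distance: 0 if inside the hull, else distance to boundary
dist_to_hull <- function(x, y, hx, hy, k) {
  inside <- TRUE
  dmin <- Inf
  for (j in seq_len(k)) {
    j2 <- if (j == k) 1L else j + 1L
    ex <- hx[j2] - hx[j]; ey <- hy[j2] - hy[j]
    # cross product sign: chull returns vertices clockwise
    cr <- ex * (y - hy[j]) - ey * (x - hx[j])
    if (cr > 1e-12) inside <- FALSE
    # distance to the segment
    len2 <- ex^2 + ey^2
    t <- if (len2 == 0) 0 else
      min(1, max(0, ((x - hx[j]) * ex + (y - hy[j]) * ey) / len2))
    dmin <- min(dmin, sqrt((x - (hx[j] + t * ex))^2 + (y - (hy[j] + t * ey))^2))
  }
  if (inside) 0 else dmin
}
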