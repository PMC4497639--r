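## Coding-space analysis: covariance PCA of a neurons x 12 selectivity
## matrix, Kaiser-Guttman component retention, canonical axis orientation,
## projection with the absolute-PC2 convention, axis-aligned linear
## separators, and resampling diagnostics.

score_colnames <- function() {
  c(paste0("direction_v", 1:4), paste0("position_v", 1:4),
    paste0("motion_v", 1:4))
}

as_score_matrix <- function(x) {
  if (inherits(x, "selectivity_vector")) x <- t(as.numeric(x))
  x <- as.matrix(x)
  if (ncol(x) != 12L)
    stop("a neurons x 12 selectivity matrix is required (columns ",
         paste(score_colnames(), collapse = ", "), ")", call. = FALSE)
  colnames(x) <- score_colnames()
  x
}

#' Fit the coding-space (covariance PCA with Kaiser-Guttman retention)
#'
#' Centers the 12 selectivity-score columns (no variance scaling: all columns
#' share the `[-1, 1]` selectivity scale), computes the principal components
#' of the covariance, and retains those whose variance fraction exceeds
#' `1/12` (about 8.3%), i.e. components explaining more variance than any
#' single original score (Kaiser-Guttman criterion).
#'
#' Axis orientations are canonicalized so the fit is deterministic: PC1 is
#' oriented so that the summed loading on the four motion scores is
#' non-positive (a movement-indifferent neuron then projects to the positive
#' side, movement-activated neurons to the negative side); PC2 so that the
#' summed loading on the position scores is non-negative (dorsal-selective
#' positive). Remaining PCs are oriented so their largest-magnitude loading
#' is positive.
#'
#' @param x neurons x 12 numeric matrix of selectivity scores in `[-1, 1]`
#'   (column order `direction_v1..v4, position_v1..v4, motion_v1..v4`), at
#'   least 3 rows.
#' @return an object of class `coding_space`: `center` (column means),
#'   `loadings` (12 x 12 orthonormal), `var_fraction` (length 12, sums to 1),
#'   `n_retained`, `thresholds` (NULL until [fit_thresholds()]), `n_neurons`.
#' @export
fit_coding_space <- function(x) {
  x <- as_score_matrix(x)
  if (nrow(x) < 3L) stop("at least 3 neurons are required", call. = FALSE)
  if (any(abs(x) > 1 + 1e-8))
    stop("selectivity scores must lie in [-1, 1]", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev > 1e-12) < 2L)
    stop("degenerate coding-space: fewer than 2 non-zero eigenvalues",
         call. = FALSE)
  frac <- ev / sum(ev)
  load <- pc$rotation
  # canonical orientation
  motion_cols <- grep("^motion", rownames(load))
  position_cols <- grep("^position", rownames(load))
  if (sum(load[motion_cols, 1]) > 0) load[, 1] <- -load[, 1]
  if (sum(load[position_cols, 2]) < 0) load[, 2] <- -load[, 2]
  for (j in 3:ncol(load)) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(center = pc$center, loadings = load, var_fraction = frac,
                 n_retained = sum(frac > 1 / 12), thresholds = NULL,
                 n_neurons = nrow(x)),
            class = "coding_space")
}

#' @export
print.coding_space <- function(x, ...) {
  cat(sprintf("<coding_space> fitted on %d neurons; %d PC(s) retained (> 1/12 of variance)\n",
              x$n_neurons, x$n_retained))
  cat(sprintf("  variance fractions: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%\n",
              100 * x$var_fraction[1], 100 * x$var_fraction[2],
              100 * x$var_fraction[3]))
  if (!is.null(x$thresholds))
    cat(sprintf("  separators: movement (PC1) at %.3f, posture (|PC2|) at %.3f\n",
                x$thresholds$movement, x$thresholds$posture))
  invisible(x)
}

#' @export
summary.coding_space <- function(object, ...) {
  print(object)
  cat("\nLoadings of the retained PCs:\n")
  print(round(object$loadings[, seq_len(max(2L, object$n_retained)),
                              drop = FALSE], 3))
  invisible(object)
}

#' Project selectivity vectors into a fitted coding-space
#'
#' Subtracts the model's column means and projects onto the loadings. The
#' posture axis uses the absolute PC2 score (ventral-selective neurons are
#' folded onto the dorsal side), following the convention that the coding
#' space reports excursion magnitude, not side.
#'
#' @param vectors a `selectivity_vector`, or a neurons x 12 matrix.
#' @param model a fitted `coding_space`.
#' @return data frame of class `coding_space_coords` with columns `pc1`
#'   (movement sensitivity), `pc2_signed`, `pc2_abs` (posture sensitivity).
#' @export
project_coding_space <- function(vectors, model) {
  if (!inherits(model, "coding_space"))
    stop("`model` must be a fitted coding_space", call. = FALSE)
  x <- as_score_matrix(vectors)
  sc <- sweep(x, 2, model$center) %*% model$loadings
  out <- data.frame(pc1 = sc[, 1], pc2_signed = sc[, 2],
                    pc2_abs = abs(sc[, 2]))
  class(out) <- c("coding_space_coords", class(out))
  out
}

#' @export
predict.coding_space <- function(object, newdata, ...) {
  project_coding_space(newdata, object)
}

#' Fit axis-aligned separator thresholds
#'
#' Places two linear separators in the coding-space from labelled training
#' coordinates: a *movement* threshold on PC1 splitting movement-activated
#' groups (ON, DP) from movement-suppressed-or-indifferent groups (OFF, SP),
#' and a *posture* threshold on |PC2| splitting position-sensitive groups
#' (SP, DP) from the motion-only groups (ON, OFF). Each threshold is the
#' midpoint of the gap between the two super-groups' extreme coordinates; if
#' the groups overlap on an axis, a warning is raised and the
#' maximum-accuracy split is used instead.
#'
#' @param coords a `coding_space_coords` data frame.
#' @param labels character vector of group labels per row; labels are matched
#'   by prefix, so `SP_d`, `SP_v` count as SP, etc. Labels outside
#'   SP/DP/ON/OFF are ignored.
#' @param model optional `coding_space`; when given, a copy with the fitted
#'   `thresholds` (and training accuracy) is returned instead of the bare
#'   threshold list.
#' @return list with `movement`, `posture`, `accuracy` (training accuracy
#'   over the four groups), or an updated `coding_space`.
#' @export
fit_thresholds <- function(coords, labels, model = NULL) {
  grp <- normalize_group(labels)
  use <- !is.na(grp)
  if (length(unique(grp[use])) < 2L)
    stop("at least two labelled groups are required", call. = FALSE)
  mov <- split_axis(coords$pc1[use], grp[use] %in% c("ON", "DP"),
                    axis = "movement")   # movers below threshold
  pos <- split_axis(coords$pc2_abs[use], grp[use] %in% c("SP", "DP"),
                    axis = "posture", low_is_true = FALSE)
  th <- list(movement = mov, posture = pos)
  pred <- classify_from_thresholds(coords[use, ], th)
  th$accuracy <- mean(pred == grp[use])
  if (is.null(model)) return(th)
  model$thresholds <- th
  model
}

normalize_group <- function(labels) {
  g <- toupper(sub("[_.].*$", "", as.character(labels)))
  g[!g %in% c("SP", "DP", "ON", "OFF")] <- NA_character_
  g
}

## midpoint-of-gap threshold between values where `is_low` should fall on the
## low side (low_is_true = TRUE) or the high side (FALSE).
split_axis <- function(v, is_low, axis, low_is_true = TRUE) {
  if (!low_is_true) is_low <- !is_low
  if (!any(is_low) || all(is_low)) {
    warning(sprintf("only one group present on the %s axis", axis),
            call. = FALSE)
    return(if (any(is_low)) max(v) + 1 else min(v) - 1)
  }
  lo <- max(v[is_low]); hi <- min(v[!is_low])
  if (lo < hi) return((lo + hi) / 2)
  warning(sprintf("groups are not separable on the %s axis; using max-accuracy split",
                  axis), call. = FALSE)
  cand <- sort(unique(v))
  cuts <- (utils::head(cand, -1) + utils::tail(cand, -1)) / 2
  acc <- vapply(cuts, function(cc) mean((v <= cc) == is_low), numeric(1))
  cuts[which.max(acc)]
}

classify_from_thresholds <- function(coords, th) {
  mover <- coords$pc1 < th$movement
  postural <- coords$pc2_abs > th$posture
  out <- ifelse(mover & postural, "DP",
         ifelse(mover & !postural, "ON",
         ifelse(!mover & postural, "SP", "OFF")))
  out[is.na(out)] <- "other"
  out
}

#' Classify coordinates into DIN groups
#'
#' Applies the model's two axis-aligned thresholds: neurons left of the
#' movement threshold (more active during movement) are ON or DP, neurons
#' above the posture threshold (position-sensitive) are SP or DP.
#'
#' @param coords a `coding_space_coords` data frame.
#' @param model a `coding_space` with fitted `thresholds` (see
#'   [fit_thresholds()]), or a bare threshold list.
#' @return character vector with values in `SP`, `DP`, `ON`, `OFF`, `other`.
#' @export
classify_coords <- function(coords, model) {
  th <- if (inherits(model, "coding_space")) model$thresholds else model
  if (is.null(th))
    stop("thresholds are not set; call fit_thresholds() first", call. = FALSE)
  classify_from_thresholds(coords, th)
}

#' Resampling diagnostics of the variance-fraction spectrum
#'
#' Re-fits the coding-space on resampled neuron sets and reports the mean and
#' SD of each PC's variance fraction across repetitions:
#' * `bootstrap50`: draw 50 neurons with replacement from all rows.
#' * `balanced6x5`: draw 6 neurons per labelled group without replacement,
#'   then 50 with replacement from that balanced pool.
#'
#' Repetitions whose draw is degenerate (fewer than two non-zero
#' eigenvalues) are skipped and counted in `n_degenerate`.
#'
#' @param x neurons x 12 selectivity matrix.
#' @param mode `"bootstrap50"` or `"balanced6x5"`.
#' @param labels group labels (required for balanced mode; every group must
#'   have >= 6 members).
#' @param reps repetitions (default 100).
#' @param seed integer seed.
#' @return list with `mean_fraction`, `sd_fraction` (length 12),
#'   `mean_loadings` (sign/order-aligned to the full-sample fit), `n_used`,
#'   `n_degenerate`, `mode`.
#' @export
resample_variance <- function(x, mode = c("bootstrap50", "balanced6x5"),
                              labels = NULL, reps = 100, seed = 1L) {
  mode <- match.arg(mode)
  x <- as_score_matrix(x)
  if (mode == "balanced6x5") {
    if (is.null(labels)) stop("balanced mode requires group labels", call. = FALSE)
    groups <- split(seq_len(nrow(x)), as.character(labels))
    small <- names(groups)[vapply(groups, length, integer(1)) < 6L]
    if (length(small))
      stop("groups with fewer than 6 members: ",
           paste(small, collapse = ", "), call. = FALSE)
  }
  ref <- fit_coding_space(x)
  fracs <- matrix(NA_real_, reps, 12)
  load_sum <- matrix(0, 12, 12)
  n_deg <- 0L
  for (r in seq_len(reps)) {
    idx <- with_seed(derive_seed(seed, r), {
      if (mode == "bootstrap50") {
        sample.int(nrow(x), 50, replace = TRUE)
      } else {
        pool <- unlist(lapply(groups, function(g) sample(g, 6L)))
        sample(pool, 50, replace = TRUE)
      }
    })
    fit <- tryCatch(fit_coding_space(x[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) { n_deg <- n_deg + 1L; next }
    fracs[r, ] <- fit$var_fraction
    load_sum <- load_sum + align_loadings(fit$loadings, ref$loadings)
  }
  used <- !is.na(fracs[, 1])
  list(mean_fraction = colMeans(fracs[used, , drop = FALSE]),
       sd_fraction = apply(fracs[used, , drop = FALSE], 2, stats::sd),
       mean_loadings = load_sum / sum(used),
       n_used = sum(used), n_degenerate = n_deg, mode = mode)
}

## permute/flip the columns of `load` to best match `ref` (PCs can swap order
## and sign between resamples); greedy by |correlation|.
align_loadings <- function(load, ref) {
  out <- matrix(0, nrow(ref), ncol(ref))
  avail <- rep(TRUE, ncol(load))
  for (j in seq_len(ncol(ref))) {
    sims <- abs(crossprod(load[, avail, drop = FALSE], ref[, j]))
    k <- which(avail)[which.max(sims)]
    s <- sign(sum(load[, k] * ref[, j]))
    if (s == 0) s <- 1
    out[, j] <- s * load[, k]
    avail[k] <- FALSE
  }
  dimnames(out) <- dimnames(ref)
  out
}

#' @export
plot.coding_space <- function(x, coords = NULL, labels = NULL, ...) {
  if (is.null(coords)) {
    graphics::plot(seq_along(x$var_fraction), 100 * x$var_fraction,
                   type = "b", xlab = "principal component",
                   ylab = "variance explained (%)", ...)
    graphics::abline(h = 100 / 12, lty = 3)
    return(invisible(x))
  }
  cols <- if (is.null(labels)) "black"
          else c(SP = "blue", DP = "cyan3", ON = "red", OFF = "darkgreen",
                 other = "grey")[
                   ifelse(is.na(normalize_group(labels)), "other",
                          normalize_group(labels))]
  graphics::plot(coords$pc1, coords$pc2_abs, col = cols, pch = 19,
                 xlab = "movement sensitivity (PC1)",
                 ylab = "posture sensitivity (|PC2|)", ...)
  if (!is.null(x$thresholds)) {
    graphics::abline(v = x$thresholds$movement, lty = 3, col = "grey40")
    graphics::abline(h = x$thresholds$posture, lty = 3, col = "grey40")
  }
  invisible(x)
}

#' Serialize / restore a coding-space model as JSON
#'
#' @param model a `coding_space`.
#' @param path output (input) file path.
#' @return `path` invisibly; `read_coding_space()` returns the model.
#' @export
write_coding_space <- function(model, path) {
  stopifnot(inherits(model, "coding_space"))
  obj <- list(center = as.numeric(model$center),
              loadings = unclass(model$loadings),
              var_fraction = model$var_fraction,
              n_retained = model$n_retained,
              thresholds = model$thresholds,
              n_neurons = model$n_neurons)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_coding_space
#' @export
read_coding_space <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- matrix(as.numeric(obj$loadings), 12, 12)
  rownames(load) <- score_colnames()
  colnames(load) <- paste0("PC", 1:12)
  structure(list(center = stats::setNames(as.numeric(obj$center),
                                          score_colnames()),
                 loadings = load,
                 var_fraction = as.numeric(obj$var_fraction),
                 n_retained = as.integer(obj$n_retained),
                 thresholds = obj$thresholds,
                 n_neurons = as.integer(obj$n_neurons)),
            class = "coding_space")
}
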