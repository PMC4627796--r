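# Rank-to-Gaussian score normalization. Each feature's scores are carried
# from their unknown empirical distribution onto a Gaussian N(mu = 0.5,
# sigma^2 = 0.01) while preserving rank (cumulative) structure, so that
# Bayes-rule fusion is not dominated by extreme values near 0 or 1.

#' Fit a normalization map for one feature
#'
#' Builds the monotone map raw score -> Gaussian N(0.5, 0.01) from a training
#' score population. The cumulative value of a score x is the empirical
#' fraction of training scores less than or equal to x (ties share one
#' cumulative value); the normalized score is
#' `qnorm(clip(ecdf(x), eps, 1 - eps)) * 0.1 + 0.5`. The clip bound
#' `epsilon` keeps outputs strictly inside (0, 1) — the Gaussian target has
#' no extreme values — and defaults to `1/(2 n)` with a floor of `1e-6`.
#'
#' @param training_scores Numeric vector of at least 100 finite raw scores.
#' @param feature Feature name the map is fitted for.
#' @param epsilon Optional clip bound in (0, 0.5).
#' @return A `norm_map` object (feature, knot table, epsilon, mu, sigma, n).
#' @seealso [apply_map()], [save_map()], [load_map()]
#' @export
fit_map <- function(training_scores, feature, epsilon = NULL) {
  x <- as.numeric(training_scores)
  if (anyNA(x) || any(!is.finite(x))) {
    abort("`training_scores` must be finite (no NA/NaN/Inf).")
  }
  n <- length(x)
  if (n < 100) {
    abort(sprintf("Need at least 100 training scores to fit a map (got %d).", n))
  }
  if (is.null(epsilon)) epsilon <- max(1 / (2 * n), 1e-6)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 || epsilon >= 0.5) {
    abort("`epsilon` must be a single value in (0, 0.5).")
  }
  s <- sort(x)
  last <- which(!duplicated(s, fromLast = TRUE)) # last index of each unique value
  knots <- tibble(raw = s[last], cum = last / n)
  structure(
    list(
      feature = as.character(feature), knots = knots,
      epsilon = epsilon, mu = 0.5, sigma = 0.1, n = n
    ),
    class = "norm_map"
  )
}

assert_norm_map <- function(map, arg = "map") {
  if (!inherits(map, "norm_map")) abort(sprintf("`%s` must be a norm_map.", arg))
  invisible(map)
}

# Vectorized raw -> normalized transform. Between knots the cumulative
# probability is interpolated linearly in the raw value; outside the training
# range the ecdf is 0 (below the minimum) or 1 (above the maximum), which the
# epsilon clip turns into the map's floor and ceiling values.
map_value <- function(map, x) {
  k <- map$knots
  if (nrow(k) >= 2) {
    cum <- approx(k$raw, k$cum, xout = x, rule = 1, ties = "ordered")$y
  } else {
    cum <- rep(NA_real_, length(x))
    cum[x == k$raw[[1]]] <- k$cum[[1]]
  }
  cum[x < k$raw[[1]]] <- 0
  cum[x > k$raw[[nrow(k)]]] <- 1
  cum <- pmin(pmax(cum, map$epsilon), 1 - map$epsilon)
  qnorm(cum) * map$sigma + map$mu
}

#' Apply a fitted normalization map to a track
#'
#' Transforms scores elementwise with the monotone map of [fit_map()] and
#' declares the result in normalized space. By default the track's feature
#' name must match the feature the map was fitted on; set
#' `check_feature = FALSE` when deliberately normalizing a derived track
#' (e.g. a freshly Bayes-combined score being re-normalized under its own
#' map, as the pipeline hierarchy requires between fusion levels).
#'
#' @param map A `norm_map`.
#' @param track A residue track.
#' @param check_feature Enforce feature-name agreement?
#' @return The track with normalized scores, `space = "normalized"` and the
#'   map's feature name.
#' @export
apply_map <- function(map, track, check_feature = TRUE) {
  assert_norm_map(map)
  assert_track(track, single_feature = TRUE, arg = "track")
  if (check_feature && track$feature[[1]] != map$feature) {
    abort(sprintf(
      "Track feature '%s' does not match the map's feature '%s'.",
      track$feature[[1]], map$feature
    ))
  }
  dplyr::mutate(track,
    feature = map$feature,
    score = map_value(map, .data$score),
    space = "normalized"
  )
}

#' @export
print.norm_map <- function(x, ...) {
  cat(sprintf(
    "<norm_map> feature '%s': %d knots from %d training scores, eps = %.3g, target N(%.2f, %.3g)\n",
    x$feature, nrow(x$knots), x$n, x$epsilon, x$mu, x$sigma^2
  ))
  invisible(x)
}

#' @export
tidy.norm_map <- function(x, ...) {
  dplyr::mutate(x$knots, normalized = qnorm(pmin(pmax(.data$cum, x$epsilon), 1 - x$epsilon)) * x$sigma + x$mu)
}

#' @export
glance.norm_map <- function(x, ...) {
  tibble(
    feature = x$feature, n = x$n, n_knots = nrow(x$knots),
    epsilon = x$epsilon, mu = x$mu, sigma = x$sigma,
    raw_min = x$knots$raw[[1]], raw_max = x$knots$raw[[nrow(x$knots)]]
  )
}

MAP_FORMAT <- "morffuse_norm_map"
MAP_VERSION <- "1"

# Full-precision number formatting: survives a write/read round trip bit-for-bit.
fmt_num <- function(x) sprintf("%.17g", x)

map_to_lines <- function(map) {
  if (nrow(map$knots) == 0) abort("Cannot save a map with no knots.")
  c(
    paste(MAP_FORMAT, MAP_VERSION, sep = "\t"),
    paste("feature", map$feature, sep = "\t"),
    paste("epsilon", fmt_num(map$epsilon), sep = "\t"),
    paste("mu", fmt_num(map$mu), sep = "\t"),
    paste("sigma", fmt_num(map$sigma), sep = "\t"),
    paste("n", map$n, sep = "\t"),
    "raw\tcum",
    paste(fmt_num(map$knots$raw), fmt_num(map$knots$cum), sep = "\t")
  )
}

map_from_lines <- function(lines, label = "map") {
  if (length(lines) < 8) abort(sprintf("%s: truncated normalization map.", label))
  hdr <- strsplit(lines[[1]], "\t")[[1]]
  if (length(hdr) != 2 || hdr[[1]] != MAP_FORMAT) {
    abort(sprintf("%s: not a morffuse normalization map.", label))
  }
  if (hdr[[2]] != MAP_VERSION) {
    abort(sprintf("%s: unsupported map version '%s'.", label, hdr[[2]]))
  }
  fields <- list()
  i <- 2
  while (i <= length(lines) && lines[[i]] != "raw\tcum") {
    kv <- strsplit(lines[[i]], "\t")[[1]]
    if (length(kv) == 2) fields[[kv[[1]]]] <- kv[[2]]
    i <- i + 1
  }
  need <- c("feature", "epsilon", "mu", "sigma", "n")
  miss <- setdiff(need, names(fields))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing field(s) %s.", label, toString(miss)))
  }
  if (i > length(lines)) abort(sprintf("%s: knot table missing.", label))
  knot_lines <- lines[seq(i + 1, length(lines))]
  knot_lines <- knot_lines[nzchar(knot_lines)]
  if (length(knot_lines) == 0) abort(sprintf("%s: empty knot table.", label))
  parts <- strsplit(knot_lines, "\t")
  if (any(lengths(parts) != 2)) abort(sprintf("%s: corrupted knot table.", label))
  raw <- as.numeric(vapply(parts, `[[`, character(1), 1))
  cum <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (anyNA(raw) || anyNA(cum)) abort(sprintf("%s: unreadable knot values.", label))
  structure(
    list(
      feature = fields$feature, knots = tibble(raw = raw, cum = cum),
      epsilon = as.numeric(fields$epsilon), mu = as.numeric(fields$mu),
      sigma = as.numeric(fields$sigma), n = as.integer(fields$n)
    ),
    class = "norm_map"
  )
}

#' Save / load a normalization map
#'
#' Maps are stored in a versioned, self-describing tab-separated text format
#' (feature name, clip bound, Gaussian target parameters, knot table) with
#' full double precision, so `load_map(save_map(m))` reproduces `apply_map`
#' outputs bit-identically.
#'
#' @param map A `norm_map`.
#' @param path File path.
#' @return `save_map` returns `path` invisibly; `load_map` returns the map.
#' @export
save_map <- function(map, path) {
  assert_norm_map(map)
  writeLines(map_to_lines(map), path)
  invisible(path)
}

#' @rdname save_map
#' @export
load_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("Map file '%s' does not exist.", path))
  map_from_lines(readLines(path, warn = FALSE), label = sprintf("Map file '%s'", path))
}
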