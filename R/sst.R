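#' Gaussian sea-surface-temperature similarity kernel
#'
#' Environmental-matching similarity of an island pair from the absolute SST
#' difference:
#' \deqn{S_{SST} = \exp\left(-\frac{\Delta T^2}{2\sigma_T^2}\right)}
#' where `sigma_t` (default 2 degrees C) controls how fast similarity decays
#' as the temperature difference grows. Values lie in (0, 1], with 1 only at
#' a zero difference; at a difference of 2 degrees C with the default scale
#' the similarity is about 0.6.
#'
#' @param delta_t Non-negative absolute SST difference(s), degrees C.
#' @param sigma_t Positive kernel scale, degrees C (default 2).
#' @return Similarity value(s) in (0, 1].
#' @export
sst_sim <- function(delta_t, sigma_t = 2) {
  if (any(delta_t < 0)) stop("delta_t must be non-negative")
  if (any(sigma_t <= 0)) stop("sigma_t must be positive")
  exp(-delta_t^2 / (2 * sigma_t^2))
}

#' Pairwise SST differences for one month
#'
#' @param sst SST tibble (`island`, `month`, `sst_c`), e.g. from
#'   [read_sst()] or [simulate_sst()].
#' @param month Month id (`"YYYY-MM"`).
#' @return Tibble of unordered pairs: `island_a`, `island_b`, `delta_t`.
#'   Islands missing this month are excluded with a warning.
#' @export
pairwise_delta <- function(sst, month) {
  sst <- tibble::as_tibble(sst)
  if (!month %in% sst$month) stop("unknown month: ", month)
  sub <- sst[sst$month == month & is.finite(sst$sst_c), , drop = FALSE]
  all_islands <- unique(sst$island)
  absent <- setdiff(all_islands, sub$island)
  if (length(absent) > 0) {
    warning("island(s) without SST in ", month, " excluded: ",
            paste(absent, collapse = ", "))
  }
  if (nrow(sub) < 2) stop("fewer than 2 islands with SST in ", month)
  sub <- sub[order(sub$island), ]
  idx <- utils::combn(nrow(sub), 2)
  tibble::tibble(
    island_a = sub$island[idx[1, ]],
    island_b = sub$island[idx[2, ]],
    delta_t = abs(sub$sst_c[idx[1, ]] - sub$sst_c[idx[2, ]])
  )
}

#' Pairwise SST similarity table
#'
#' Combines [pairwise_delta()] and [sst_sim()] over one month or all months.
#'
#' @inheritParams pairwise_delta
#' @param month Month id, or `NULL` for every month in `sst`.
#' @param sigma_t Kernel scale, degrees C (default 2).
#' @return Tibble `island_a`, `island_b`, `month`, `delta_t`, `s_sst`.
#' @export
sst_similarity <- function(sst, month = NULL, sigma_t = 2) {
  months <- if (is.null(month)) sort(unique(sst$month)) else month
  purrr::map_dfr(months, function(m) {
    d <- pairwise_delta(sst, m)
    d$month <- m
    d$s_sst <- sst_sim(d$delta_t, sigma_t)
    d[, c("island_a", "island_b", "month", "delta_t", "s_sst")]
  })
}

#' Monthly groups of pairwise SST similarities
#'
#' One group per month containing every island pair with SST data that
#' month; the seasonal comparison ([seasonal_comparison()]) tests these
#' groups. Months with no computable pair are dropped with a warning.
#'
#' @inheritParams sst_similarity
#' @return Tibble `month`, `island_a`, `island_b`, `s_sst` (long format).
#' @export
monthly_similarity_groups <- function(sst, sigma_t = 2) {
  months <- sort(unique(sst$month))
  purrr::map_dfr(months, function(m) {
    d <- tryCatch(sst_similarity(sst, m, sigma_t),
                  error = function(e) {
                    warning("month ", m, " excluded: ", conditionMessage(e))
                    NULL
                  })
    if (is.null(d)) return(NULL)
    d[, c("month", "island_a", "island_b", "s_sst")]
  })
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Thin tidy wrapper over [stats::kruskal.test()] (tie-corrected H,
#' chi-squared reference with k - 1 degrees of freedom).
#'
#' @param data A data frame.
#' @param value,group Tidy-eval columns holding the response and the group.
#' @return One-row tibble `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  stopifnot(length(v) == length(g))
  if (length(unique(g)) < 2) stop("need at least 2 groups")
  if (length(unique(v)) == 1) {
    return(tibble::tibble(statistic = 0,
                          df = length(unique(g)) - 1, p_value = 1))
  }
  kt <- stats::kruskal.test(v, factor(g))
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Dunn's post hoc pairwise comparisons
#'
#' All pairwise z statistics from pooled tie-corrected ranks,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}}
#' with two-sided normal p-values, multiplicity-adjusted (Benjamini-Hochberg
#' by default) and annotated with significance stars (* < 0.05, ** < 0.01,
#' *** < 0.001 on the adjusted p).
#'
#' @inheritParams kruskal_wallis
#' @param adjust Adjustment method for [stats::p.adjust()] (default `"BH"`).
#' @return Tibble `group1`, `group2`, `z`, `p_value`, `p_adjusted`, `stars`.
#' @export
dunn_posthoc <- function(data, value, group, adjust = "BH") {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (any(tabulate(g, nbins = nlevels(g)) == 0)) {
    stop("every group needs at least one value")
  }
  N <- length(v)
  r <- rank(v)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_corr
  rbar <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  lev <- levels(g)
  idx <- utils::combn(length(lev), 2)
  if (var_term <= 0) {
    # every value tied: no rank information, all comparisons null
    z <- rep(0, ncol(idx))
  } else {
    z <- (rbar[idx[1, ]] - rbar[idx[2, ]]) /
      sqrt(var_term * (1 / n_g[idx[1, ]] + 1 / n_g[idx[2, ]]))
  }
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = adjust)
  stars <- dplyr::case_when(
    p_adj < 0.001 ~ "***",
    p_adj < 0.01 ~ "**",
    p_adj < 0.05 ~ "*",
    TRUE ~ ""
  )
  tibble::tibble(group1 = lev[idx[1, ]], group2 = lev[idx[2, ]],
                 z = as.numeric(z), p_value = as.numeric(p),
                 p_adjusted = as.numeric(p_adj), stars = stars)
}

#' Seasonal comparison of SST similarity across months
#'
#' Builds the monthly similarity groups, runs the Kruskal-Wallis omnibus
#' test, Dunn's pairwise post hoc with Benjamini-Hochberg adjustment, and
#' reports monthly medians.
#'
#' @inheritParams sst_similarity
#' @return A `seasonal_comparison`: list with `kw` (one-row tibble),
#'   `pairwise` (Dunn table), `medians` (per-month median similarity),
#'   `sigma_t`.
#' @export
seasonal_comparison <- function(sst, sigma_t = 2) {
  groups <- monthly_similarity_groups(sst, sigma_t)
  kw <- kruskal_wallis(groups, s_sst, month)
  pw <- dunn_posthoc(groups, s_sst, month)
  med <- groups |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(median_s_sst = stats::median(.data$s_sst),
                     n_pairs = dplyr::n(), .groups = "drop")
  structure(list(kw = kw, pairwise = pw, medians = med, sigma_t = sigma_t,
                 groups = groups),
            class = "seasonal_comparison")
}

#' @export
print.seasonal_comparison <- function(x, ...) {
  cat(sprintf(
    "Seasonal SST-similarity comparison: Kruskal-Wallis chi-squared = %.2f, df = %d, p = %.3g\n",
    x$kw$statistic, x$kw$df, x$kw$p_value
  ))
  top <- x$medians[order(-x$medians$median_s_sst), ]
  cat("  highest-median month:", top$month[1],
      sprintf("(median %.3f)\n", top$median_s_sst[1]))
  invisible(x)
}

#' @rdname seasonal_comparison
#' @param x A `seasonal_comparison`.
#' @param ... Unused.
#' @export
tidy.seasonal_comparison <- function(x, ...) x$pairwise

#' @rdname seasonal_comparison
#' @export
glance.seasonal_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$kw$statistic, df = x$kw$df,
                 p_value = x$kw$p_value, n_months = nrow(x$medians),
                 sigma_t = x$sigma_t)
}

#' Month with the highest median SST similarity
#'
#' Ties are broken by the earliest calendar month.
#'
#' @param comparison A `seasonal_comparison`.
#' @return Month id.
#' @export
best_similarity_month <- function(comparison) {
  med <- comparison$medians[order(comparison$medians$month), ]
  med$month[which.max(med$median_s_sst)]
}

#' Build the SST-composite network
#'
#' Multiplies every directed edge's trip frequency by the SST similarity of
#' its endpoint pair for the chosen month, yielding composite weights
#' (propagule pressure x establishment suitability). The edge set and node
#' degrees are unchanged; weights can only shrink.
#'
#' @param net A directed `vessel_network` with trip-frequency weights.
#' @param sim A similarity table from [sst_similarity()].
#' @param month Month id; defaults to the single month present in `sim`.
#' @return A `composite_network` (also a `vessel_network`) whose edge table
#'   carries `weight` (composite), `frequency` and `s_sst` columns, with
#'   attribute `month`.
#' @export
composite_network <- function(net, sim, month = NULL) {
  stopifnot(inherits(net, "vessel_network"), net$directed)
  sim <- tibble::as_tibble(sim)
  if (is.null(month)) {
    month <- unique(sim$month)
    if (length(month) != 1) stop("sim covers several months; pick one")
  }
  sim <- sim[sim$month == month, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  s <- stats::setNames(sim$s_sst, key(sim$island_a, sim$island_b))
  ek <- key(net$edges$origin, net$edges$destination)
  miss <- is.na(s[ek])
  if (any(miss)) {
    stop("no SST similarity for connected pair(s) in ", month, ": ",
         paste(unique(gsub("\r", "-", ek[miss])), collapse = ", "))
  }
  edges <- net$edges
  edges$frequency <- edges$weight
  edges$s_sst <- unname(s[ek])
  edges$weight <- edges$frequency * edges$s_sst
  out <- vessel_network(edges[, c("origin", "destination", "weight")],
                        islands = net$nodes, directed = TRUE)
  ord <- match(paste(out$edges$origin, out$edges$destination),
               paste(edges$origin, edges$destination))
  out$edges$frequency <- edges$frequency[ord]
  out$edges$s_sst <- edges$s_sst[ord]
  attr(out, "month") <- month
  class(out) <- c("composite_network", class(out))
  out
}

#' Export a similarity table as TSV
#' @param sim A similarity table from [sst_similarity()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  readr::write_tsv(sim, path)
  invisible(path)
}
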