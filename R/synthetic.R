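#' Define a synthetic archipelago scenario
#'
#' Parameters of the generator that emulates the statistical structure the
#' pipeline expects from real inter-island traffic: ~23 islands of which ~19
#' carry traffic, on the order of 12,000 annual trips concentrated on one
#' dominant hub, roughly 55% of trips reciprocal, a locally clustered
#' backbone with a few long-range rewired routes (small-world structure),
#' five latitude-banded SST zones, and 12 monthly SST fields with seasonal
#' and latitudinal structure whose inter-island spread itself varies through
#' the year (largest in the cool season).
#'
#' @param n_islands Number of islands (default 23).
#' @param n_connected Number of islands carrying traffic (default 19; the
#'   rest stay isolated).
#' @param n_trips Total annual trips (default 12000).
#' @param hub_bias Share of trips carried by hub-incident pairs (default
#'   0.4).
#' @param reciprocity_target Target trip-weighted reciprocity (default
#'   0.55); approached stochastically, not enforced exactly.
#' @param rewiring_p Probability a backbone lattice edge is rewired to a
#'   random pair (default 0.1).
#' @param n_zones Number of latitude-banded SST zones (default 5).
#' @param sst_mean Archipelago mean SST, degrees C (default 24).
#' @param seasonal_amplitude Seasonal SST swing, degrees C (default 2).
#' @param latitudinal_gradient SST change per degree latitude, degrees C
#'   (default 2).
#' @param gradient_seasonality Relative seasonal modulation of the
#'   latitudinal gradient in \[0, 1) (default 0.5); the gradient peaks half a
#'   year after the warm-season peak, so inter-island spread is largest in
#'   the cool season.
#' @param sst_noise_sd SD of island-month SST noise, degrees C (default 0.4).
#' @param months Month ids of the 12-month window (default Feb 2015 - Jan
#'   2016).
#' @param seed Integer RNG seed (mandatory).
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_islands = 23, n_connected = 19,
                               n_trips = 12000, hub_bias = 0.4,
                               reciprocity_target = 0.55, rewiring_p = 0.1,
                               n_zones = 5, sst_mean = 24,
                               seasonal_amplitude = 2,
                               latitudinal_gradient = 2,
                               gradient_seasonality = 0.5,
                               sst_noise_sd = 0.4,
                               months = month_window("2015-02", "2016-01"),
                               seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(
    n_islands >= 2, n_connected >= 2, n_connected <= n_islands,
    n_trips > 0, hub_bias >= 0, hub_bias <= 1,
    reciprocity_target >= 0, reciprocity_target <= 1,
    rewiring_p >= 0, rewiring_p <= 1,
    n_zones >= 1, n_zones <= n_islands,
    sst_noise_sd >= 0, gradient_seasonality >= 0, gradient_seasonality < 1
  )
  structure(
    list(n_islands = n_islands, n_connected = n_connected, n_trips = n_trips,
         hub_bias = hub_bias, reciprocity_target = reciprocity_target,
         rewiring_p = rewiring_p, n_zones = n_zones, sst_mean = sst_mean,
         seasonal_amplitude = seasonal_amplitude,
         latitudinal_gradient = latitudinal_gradient,
         gradient_seasonality = gradient_seasonality,
         sst_noise_sd = sst_noise_sd, months = months,
         seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' Simulate island metadata
#'
#' Places islands uniformly in a bounding box resembling an equatorial
#' archipelago (lat -1.5..0.7, lon -92..-89) and assigns SST zones as
#' latitude bands (zone 1 southernmost), each band non-empty.
#'
#' @param scn A `synthetic_scenario`.
#' @return Island tibble (`island`, `lat`, `lon`, `harris_zone`).
#' @export
simulate_islands <- function(scn) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed)
  n <- scn$n_islands
  lat <- stats::runif(n, -1.5, 0.7)
  lon <- stats::runif(n, -92, -89)
  zone <- ceiling(rank(lat, ties.method = "first") * scn$n_zones / n)
  tibble::tibble(
    island = sprintf("Island%02d", seq_len(n)),
    lat = lat, lon = lon,
    harris_zone = as.integer(zone)
  )
}

#' Simulate monthly island SST fields
#'
#' \deqn{SST(i, m) = \mu + A\cos(2\pi(m - m_{peak})/12) +
#'   g_m\,lat_i + \epsilon_{im}}
#' with an archipelago-wide seasonal cycle (amplitude `seasonal_amplitude`,
#' peak in the second month of the window) and a latitudinal gradient whose
#' strength is seasonally modulated,
#' \eqn{g_m = g (1 + \kappa \cos(2\pi(m - m_{peak} - 6)/12))}, so the
#' inter-island SST spread — and hence pairwise similarity — varies across
#' months. Noise is iid normal with SD `sst_noise_sd`.
#'
#' @param scn A `synthetic_scenario`.
#' @param islands Island tibble from [simulate_islands()].
#' @return SST tibble (`island`, `month`, `sst_c`), 12 months per island.
#' @export
simulate_sst <- function(scn, islands) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed + 1L)
  peak <- 2
  grid <- tidyr::expand_grid(island = islands$island,
                             month_idx = seq_along(scn$months))
  grid$month <- scn$months[grid$month_idx]
  lat <- stats::setNames(islands$lat, islands$island)
  g_m <- scn$latitudinal_gradient *
    (1 + scn$gradient_seasonality *
       cos(2 * pi * (grid$month_idx - peak - 6) / 12))
  grid$sst_c <- scn$sst_mean +
    scn$seasonal_amplitude * cos(2 * pi * (grid$month_idx - peak) / 12) +
    g_m * unname(lat[grid$island]) +
    stats::rnorm(nrow(grid), 0, scn$sst_noise_sd)
  tibble::as_tibble(grid[, c("island", "month", "sst_c")])
}

#' Simulate trip records
#'
#' Builds a traffic backbone over the connected islands: a ring lattice
#' ordered by latitude (each island linked to its two nearest ring
#' neighbours on either side, giving local clustering), rewired with
#' probability `rewiring_p` per lattice edge (short global paths), plus
#' spokes from the hub (the first island) to every connected island. Trips
#' are allocated over backbone pairs so hub-incident pairs carry about
#' `hub_bias` of the total; a randomised subset of pairs whose expected
#' traffic sums to `reciprocity_target` is served in both directions, the
#' rest one-way. Counts are spread uniformly over the 12 months. The total
#' count equals `n_trips` exactly and exactly `n_islands - n_connected`
#' islands stay isolated.
#'
#' @param scn A `synthetic_scenario`.
#' @param islands Island tibble from [simulate_islands()].
#' @return Trip-record tibble (`origin`, `destination`, `month`, `count`).
#' @export
simulate_traffic <- function(scn, islands) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed + 2L)
  conn <- islands$island[seq_len(scn$n_connected)]
  hub <- conn[1]
  ring <- conn[order(islands$lat[match(conn, islands$island)])]
  nc <- length(ring)
  # ring lattice, neighbours at offset 1 and 2
  pairs <- rbind(
    cbind(ring, ring[c(2:nc, 1)]),
    if (nc > 4) cbind(ring, ring[c(3:nc, 1, 2)])
  )
  pairs <- t(apply(pairs, 1, sort))
  pairs <- unique(pairs)
  # rewire lattice edges with probability rewiring_p
  for (i in seq_len(nrow(pairs))) {
    if (stats::runif(1) < scn$rewiring_p) {
      for (try in 1:20) {
        cand <- sort(sample(ring, 2))
        dup <- any(pairs[-i, 1] == cand[1] & pairs[-i, 2] == cand[2])
        if (!dup) {
          pairs[i, ] <- cand
          break
        }
      }
    }
  }
  # hub spokes to every other connected island
  spokes <- t(vapply(setdiff(ring, hub),
                     function(x) sort(c(hub, x)), character(2)))
  pairs <- unique(rbind(pairs, spokes))
  hub_pair <- pairs[, 1] == hub | pairs[, 2] == hub
  n_pairs <- nrow(pairs)
  # allocation probabilities: hub pairs share hub_bias of the traffic
  prob <- numeric(n_pairs)
  prob[hub_pair] <- scn$hub_bias / sum(hub_pair)
  prob[!hub_pair] <- (1 - scn$hub_bias) / sum(!hub_pair)
  # 2 guaranteed trips per pair; remainder multinomial
  base <- 2L
  n_free <- scn$n_trips - base * n_pairs
  if (n_free < 0) stop("n_trips too small for the backbone (need >= ",
                       2 * n_pairs, ")")
  alloc <- base + as.vector(stats::rmultinom(1, n_free, prob))
  # reciprocal pairs: randomised greedy subset with expected trip share
  # ~ reciprocity_target
  ord <- sample.int(n_pairs)
  cum <- cumsum(prob[ord])
  k <- sum(cum <= scn$reciprocity_target + 1e-12)
  # take one more pair when that lands the expected share closer to target
  if (k < n_pairs) {
    below <- if (k == 0) 0 else cum[k]
    if (abs(cum[k + 1] - scn$reciprocity_target) <
        abs(below - scn$reciprocity_target)) {
      k <- k + 1
    }
  }
  recip <- logical(n_pairs)
  if (k > 0) recip[ord[seq_len(k)]] <- TRUE
  # split pair totals over directions
  fwd_first <- stats::runif(n_pairs) < 0.5
  a <- ifelse(fwd_first, pairs[, 1], pairs[, 2])
  b <- ifelse(fwd_first, pairs[, 2], pairs[, 1])
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    if (recip[i]) {
      fwd <- 1L + stats::rbinom(1, alloc[i] - 2L, 0.5)
      dirs <- tibble::tibble(origin = c(a[i], b[i]),
                             destination = c(b[i], a[i]),
                             count = c(fwd, alloc[i] - fwd))
    } else {
      dirs <- tibble::tibble(origin = a[i], destination = b[i],
                             count = alloc[i])
    }
    out[[i]] <- dirs
  }
  directed <- dplyr::bind_rows(out)
  # spread each directed edge's count uniformly over months
  n_m <- length(scn$months)
  records <- purrr::pmap_dfr(directed, function(origin, destination, count) {
    per_month <- as.vector(stats::rmultinom(1, count, rep(1 / n_m, n_m)))
    keep <- per_month > 0
    tibble::tibble(origin = origin, destination = destination,
                   month = scn$months[keep], count = per_month[keep])
  })
  dplyr::arrange(records, .data$origin, .data$destination, .data$month)
}

#' Simulate a complete scenario
#'
#' Convenience wrapper returning islands, SST and trip records together.
#'
#' @param scn A `synthetic_scenario`.
#' @return List with `islands`, `sst`, `trips`, `scenario`.
#' @export
simulate_scenario <- function(scn) {
  islands <- simulate_islands(scn)
  list(islands = islands,
       sst = simulate_sst(scn, islands),
       trips = simulate_traffic(scn, islands),
       scenario = scn)
}

#' Write scenario fixtures to disk
#'
#' Writes `trips.csv`, `islands.csv`, `sst.csv` in the dialects consumed by
#' [read_trip_records()], [read_islands()] and [read_sst()], plus
#' `manifest.json` recording every scenario parameter and the seed.
#'
#' @param scn A `synthetic_scenario`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixtures <- function(scn, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  sim <- simulate_scenario(scn)
  paths <- c(
    trips = file.path(out_dir, "trips.csv"),
    islands = file.path(out_dir, "islands.csv"),
    sst = file.path(out_dir, "sst.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(sim$trips, paths["trips"])
  readr::write_csv(sim$islands, paths["islands"])
  readr::write_csv(sim$sst, paths["sst"])
  manifest <- unclass(scn)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a scenario back from a manifest
#' @param path Path to a `manifest.json` written by [write_fixtures()].
#' @return A `synthetic_scenario`.
#' @export
read_scenario_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_scenario, m)
}
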