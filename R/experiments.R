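#' Capacity experiment: anchor collisions vs the birthday bound
#'
#' Empirically measures how the chance that two randomly anchored
#' objects share a discretized location key falls as modules are added.
#' For each module count, many trials each draw `n_anchors` random
#' anchors and record whether any two collide; the empirical collision
#' rate is reported next to the birthday approximation
#' `1 - exp(-N^2 / (2 * capacity))`.
#'
#' Anchor keys are drawn by a vectorized sampler (uniform phases binned
#' per module, combined mixed-radix) — the same generative process as
#' `discretize(random_code(ms))`, at the scale 10,000 trials need.
#'
#' @param n_modules Integer vector of module counts to test.
#' @param bins Cells per lattice axis for every module (capacity per
#'   module is `bins^2`).
#' @param n_anchors Anchors drawn per trial (the "N" of the birthday
#'   bound).
#' @param n_trials Trials per module count.
#' @param seed RNG seed.
#' @return A tibble of class `capacity_report`: `n_modules`, `capacity`,
#'   `n_anchors`, `n_trials`, `collision_rate`, `predicted`, `se`
#'   (binomial standard error at the predicted rate).
#' @examples
#' experiment_capacity(n_modules = 1:2, bins = 5, n_anchors = 2,
#'                     n_trials = 500, seed = 1)
#' @export
experiment_capacity <- function(n_modules = 1:3, bins = 5L,
                                n_anchors = 2L, n_trials = 1000L,
                                seed = 1L) {
  set.seed(seed)
  rows <- lapply(n_modules, function(m) {
    cap <- as.double(bins)^(2 * m)
    total <- n_trials * n_anchors
    key <- numeric(total)
    for (j in seq_len(m)) {
      ia <- floor(stats::runif(total) * bins)
      ib <- floor(stats::runif(total) * bins)
      key <- key * bins^2 + ia * bins + ib
    }
    keys <- matrix(key, nrow = n_trials)
    hit <- apply(keys, 1, anyDuplicated) > 0
    pred <- 1 - exp(-as.double(n_anchors)^2 / (2 * cap))
    tibble::tibble(
      n_modules = m, capacity = cap, n_anchors = n_anchors,
      n_trials = n_trials, collision_rate = mean(hit),
      predicted = pred, se = sqrt(pred * (1 - pred) / n_trials)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("capacity_report", class(tibble::tibble()))
  out
}

#' Recognition experiment: sensations to consensus
#'
#' Builds a random object library, then repeatedly drops sensor columns
#' onto a target object and counts the sensations needed for every
#' column to recognize it, for each column count in `cfg$n_columns`.
#' Arms with different column counts run on identical per-trial seeds,
#' targets and start points (extra columns extend the single-column
#' setup), so column counts are compared paired.
#'
#' @param cfg A [world_config()].
#' @return A tibble of class `recognition_report` with columns `trial`,
#'   `n_objects`, `n_columns`, `seed`, `sensations`, `outcome`
#'   (`"recognized"` / `"failed"`); the config hash is attached as the
#'   `config_hash` attribute.  Summaries via [glance()].
#' @examples
#' cfg <- world_config(seed = 1, n_objects = 5, n_features = 4,
#'                     n_trials = 3, ms = default_module_set(3))
#' experiment_recognition(cfg)
#' @export
experiment_recognition <- function(cfg) {
  set.seed(cfg$seed)
  world <- build_world(cfg)
  ids <- names(world$placements)
  max_cols <- max(cfg$n_columns)
  trials <- tibble::tibble(
    trial = seq_len(cfg$n_trials),
    target = ids[(seq_len(cfg$n_trials) - 1L) %% length(ids) + 1L],
    tour_seed = sample.int(.Machine$integer.max, cfg$n_trials)
  )
  base_col <- column(cfg$ms, world$lib)
  rows <- list()
  for (t in seq_len(cfg$n_trials)) {
    target <- trials$target[t]
    pl <- world$placements[[target]]
    set.seed(trials$tour_seed[t])
    starts <- rep(sample.int(nrow(pl)), length.out = max_cols)
    for (nc in cfg$n_columns) {
      net <- column_network(rep(list(base_col), nc))
      # Same per-trial seed for every arm: column 1's tour is identical
      # whether it runs alone or alongside voting columns.
      set.seed(trials$tour_seed[t])
      sens <- sensations_to_recognition(
        net, target, pl, start_indices = starts[seq_len(nc)],
        max_sensations = cfg$max_sensations
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial = t, n_objects = cfg$n_objects, n_columns = nc,
        seed = cfg$seed, sensations = sens,
        outcome = if (is.na(sens)) "failed" else "recognized"
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config_hash") <- cfg$hash
  class(out) <- c("recognition_report", class(tibble::tibble()))
  out
}

#' Navigation experiment: decode the vector from a to b
#'
#' Anchors an environment with a random code, draws point pairs (a, b),
#' encodes both by path integration from the anchor, takes their
#' displacement code, decodes it back to a motor vector, and measures
#' the arrival error after moving that vector from a.  Pairs whose true
#' offset exceeds the decodable radius are counted as `"undecodable"`,
#' not errors.
#'
#' @param ms Module set; the default pairs integer periods 3 and 4
#'   (joint period 12, uniquely decodable within radius 6).
#' @param n_trials Number of point pairs.
#' @param extent Points are drawn from the integer box
#'   `0..(extent-1)` squared.
#' @param max_offset b is at most this far from a per axis (integer
#'   offsets).
#' @param search_radius,grid_step Passed to [decode_vector()].
#' @param seed RNG seed.
#' @return A tibble of class `navigation_report`: `trial`, `ax`, `ay`,
#'   `bx`, `by`, `vx`, `vy`, `arrival_error`, `outcome`.
#' @examples
#' experiment_navigation(n_trials = 5, seed = 1)
#' @export
experiment_navigation <- function(ms = module_set(scale = c(3, 4),
                                                  bins_a = c(3L, 4L),
                                                  bins_b = c(3L, 4L)),
                                  n_trials = 100L, extent = 10L,
                                  max_offset = 5L, search_radius = 6,
                                  grid_step = 1, seed = 1L) {
  set.seed(seed)
  anchor <- random_code(ms, frame = "environment")
  rows <- lapply(seq_len(n_trials), function(t) {
    a <- c(sample.int(extent, 1L) - 1L, sample.int(extent, 1L) - 1L)
    off <- c(sample.int(2L * max_offset + 1L, 1L) - max_offset - 1L,
             sample.int(2L * max_offset + 1L, 1L) - max_offset - 1L)
    b <- a + off
    code_a <- integrate_code(anchor, ms, a)
    code_b <- integrate_code(anchor, ms, b)
    d <- displacement_between(code_a, code_b, ms)
    res <- tryCatch(
      decode_vector(d, ms, search_radius = search_radius,
                    grid_step = grid_step),
      cortexgrid_undecodable = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(trial = t, ax = a[1], ay = a[2], bx = b[1],
                     by = b[2], vx = NA_real_, vy = NA_real_,
                     arrival_error = NA_real_, outcome = "undecodable")
    } else {
      err <- sqrt(sum((a + c(res$vx, res$vy) - b)^2))
      tibble::tibble(trial = t, ax = a[1], ay = a[2], bx = b[1],
                     by = b[2], vx = res$vx, vy = res$vy,
                     arrival_error = err, outcome = "decoded")
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("navigation_report", class(tibble::tibble()))
  out
}
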