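ms4 <- default_module_set(4)

two_object_lib <- function(ms) {
  # identical at the origin, distinguishable one step right
  lib <- learn_object(object_library(), "objA",
                      waypoint_trace(rbind(c(0, 0), c(1, 0)),
                                     c("shared", "plain")), ms)
  learn_object(lib, "objB",
               waypoint_trace(rbind(c(0, 0), c(1, 0)),
                              c("shared", "quilted")), ms)
}

test_that("a sensed feature activates the union of stored poses", {
  set.seed(51)
  lib <- two_object_lib(ms4)
  col <- column(ms4, lib)
  expect_identical(n_hypotheses(init_from_feature(col, "shared")), 2L)
  expect_identical(n_hypotheses(init_from_feature(col, "plain")), 1L)
  expect_identical(n_hypotheses(init_from_feature(col, "velvet")), 0L)

  # feature occurring at three keys across two objects -> 3 hypotheses
  lib3 <- learn_object(lib, "objC",
                       waypoint_trace(rbind(c(0, 0), c(2, 2)),
                                      c("plain", "plain")), ms4)
  col3 <- column(ms4, lib3)
  expect_identical(n_hypotheses(init_from_feature(col3, "plain")), 3L)
  expect_setequal(hypotheses(init_from_feature(col3, "plain"))$object_id,
                  c("objA", "objC", "objC"))
})

test_that("movement plus sensation eliminates inconsistent hypotheses", {
  set.seed(52)
  lib <- two_object_lib(ms4)
  col <- init_from_feature(column(ms4, lib), "shared")

  # null step changes nothing
  expect_identical(hypotheses(column_step(col, c(0, 0), "none")),
                   hypotheses(col))

  stepped <- column_step(col, c(1, 0), "plain")
  expect_identical(hypotheses(stepped)$object_id, "objA")
  expect_identical(recognized(stepped), "objA")

  contradicted <- column_step(col, c(1, 0), "velvet")
  expect_identical(n_hypotheses(contradicted), 0L)
  expect_identical(recognized(contradicted), "undecided")

  # empty state passes through
  expect_identical(n_hypotheses(column_step(contradicted, c(1, 0),
                                            "plain")), 0L)
})

test_that("strict mode prunes unvisited predictions, lenient keeps them", {
  set.seed(53)
  lib <- two_object_lib(ms4)
  strict <- init_from_feature(column(ms4, lib), "shared")
  lenient <- init_from_feature(column(ms4, lib, mode = "lenient"),
                               "shared")
  # moving somewhere neither object stored, then sensing a feature of
  # objA only at that spot: strict drops both, lenient keeps both
  strict2 <- column_step(strict, c(5, 5), "plain")
  lenient2 <- column_step(lenient, c(5, 5), "plain")
  expect_identical(n_hypotheses(strict2), 0L)
  expect_identical(n_hypotheses(lenient2), 2L)
})

test_that("recognized reports homogeneous non-empty candidate sets", {
  set.seed(54)
  lib <- two_object_lib(ms4)
  col <- init_from_feature(column(ms4, lib), "shared")
  expect_identical(recognized(col), "undecided")
  expect_identical(recognized(init_from_feature(col, "plain")), "objA")
  expect_identical(recognized(column(ms4, lib)), "undecided")
})

test_that("columns vote by intersecting their object sets", {
  set.seed(55)
  ms <- ms4
  lib <- learn_object(object_library(), "X",
                      waypoint_trace(rbind(c(0, 0), c(1, 1)),
                                     c("f", "g")), ms)
  lib <- learn_object(lib, "Y", waypoint_trace(rbind(c(0, 0)), "f"), ms)
  lib <- learn_object(lib, "Z", waypoint_trace(rbind(c(0, 0)), "g"), ms)

  c1 <- init_from_feature(column(ms, lib), "f") # {X, Y}
  c2 <- init_from_feature(column(ms, lib), "g") # {X, Z}
  net <- vote(column_network(list(c1, c2)))
  expect_false(net$disagreement)
  expect_identical(recognized(net$columns[[1]]), "X")
  expect_identical(recognized(net$columns[[2]]), "X")

  # disjoint sets: disagreement flagged, states untouched
  lib2 <- learn_object(lib, "W", waypoint_trace(rbind(c(0, 0)), "h"), ms)
  d1 <- init_from_feature(column(ms, lib2), "h") # {W}
  d2 <- init_from_feature(column(ms, lib2), "f") # {X, Y}
  net2 <- vote(column_network(list(d1, d2)))
  expect_true(net2$disagreement)
  expect_identical(n_hypotheses(net2$columns[[1]]), 1L)
  expect_identical(n_hypotheses(net2$columns[[2]]), 2L)

  # single column: no-op
  net3 <- vote(column_network(list(c1)))
  expect_identical(n_hypotheses(net3$columns[[1]]),
                   n_hypotheses(c1))

  # empty columns abstain rather than zeroing the consensus
  e1 <- init_from_feature(column(ms, lib), "unknown-feature")
  net4 <- vote(column_network(list(e1, c1)))
  expect_false(net4$disagreement)
  expect_identical(n_hypotheses(net4$columns[[2]]), n_hypotheses(c1))
})

test_that("the true pose survives noiseless sensing (soundness)", {
  set.seed(56)
  for (rep in 1:5) {
    cfg <- world_config(seed = 560 + rep, ms = ms4, n_objects = 6,
                        n_features = 5, alphabet_size = 4,
                        n_trials = 1)
    world <- build_world(cfg)
    target <- "obj003"
    pl <- world$placements[[target]]
    col <- init_from_feature(column(ms4, world$lib), pl$feature[1])
    n_prev <- n_hypotheses(col)
    for (i in 2:nrow(pl)) {
      move <- c(pl$x[i] - pl$x[i - 1], pl$y[i] - pl$y[i - 1])
      col <- column_step(col, move, pl$feature[i])
      # candidate set never grows
      expect_lte(n_hypotheses(col), n_prev)
      n_prev <- n_hypotheses(col)
      # the true object is always among the survivors
      expect_true(target %in% hypotheses(col)$object_id)
    }
  }
})

test_that("surviving hypotheses match a brute-force history check", {
  # oracle: test every (object, stored key) pose against the full
  # observation history using exact phase arithmetic
  set.seed(57)
  cfg <- world_config(seed = 57, ms = ms4, n_objects = 4, n_features = 4,
                      alphabet_size = 3, n_trials = 1)
  world <- build_world(cfg)
  target <- "obj002"
  pl <- world$placements[[target]]
  history <- list() # (movement, sensed) pairs after the initial sensation
  col <- init_from_feature(column(ms4, world$lib), pl$feature[1])
  for (i in 2:nrow(pl)) {
    move <- c(pl$x[i] - pl$x[i - 1], pl$y[i] - pl$y[i - 1])
    history[[length(history) + 1]] <- list(move = move,
                                           sensed = pl$feature[i])
    col <- column_step(col, move, pl$feature[i])
  }
  oracle <- character()
  for (id in names(world$lib$objects)) {
    model <- get_object(world$lib, id)
    hit <- names(model$features)[model$features == pl$feature[1]]
    for (key in hit) {
      loc <- model$locations[[key]]
      alive <- TRUE
      for (h in history) {
        loc <- integrate_code(loc, ms4, h$move)
        if (!identical(feature_at(world$lib, id, loc, ms4), h$sensed)) {
          alive <- FALSE
          break
        }
      }
      if (alive) {
        oracle <- c(oracle, paste(id, key_string(discretize(loc, ms4))))
      }
    }
  }
  got <- hypotheses(col)
  expect_setequal(paste(got$object_id, got$key), oracle)
})

test_that("sensations_to_recognition counts to consensus", {
  set.seed(58)
  # a library of exactly one object is recognized at the first sensation
  solo <- learn_object(object_library(), "only",
                       waypoint_trace(rbind(c(0, 0), c(1, 0)),
                                      c("a", "b")), ms4)
  pl_solo <- tibble::tibble(x = c(0L, 1L), y = c(0L, 0L),
                            feature = c("a", "b"))
  net <- column_network(list(column(ms4, solo)))
  expect_identical(
    sensations_to_recognition(net, "only", pl_solo, start_indices = 1L),
    1L
  )

  # two objects sharing the first-sensed feature need a second sensation
  lib <- two_object_lib(ms4)
  pl <- tibble::tibble(x = c(0L, 1L), y = c(0L, 0L),
                       feature = c("shared", "plain"))
  net <- column_network(list(column(ms4, lib)))
  expect_identical(
    sensations_to_recognition(net, "objA", pl, start_indices = 1L),
    2L
  )

  # columns starting on features unique to the target vote to consensus
  # in a single sensation
  lib2 <- learn_object(lib, "objT",
                       waypoint_trace(rbind(c(0, 0), c(2, 0)),
                                      c("unique1", "unique2")), ms4)
  pl2 <- tibble::tibble(x = c(0L, 2L), y = c(0L, 0L),
                        feature = c("unique1", "unique2"))
  net2 <- column_network(list(column(ms4, lib2), column(ms4, lib2)))
  expect_identical(
    sensations_to_recognition(net2, "objT", pl2,
                              start_indices = c(1L, 2L)),
    1L
  )
})
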