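test_that("learning stores features at discretized visited locations", {
  ms <- default_module_set(4)
  set.seed(31)

  none_only <- waypoint_trace(rbind(c(1, 0), c(2, 2)), c("none", "none"))
  lib <- learn_object(object_library(), "blank", none_only, ms)
  expect_length(get_object(lib, "blank")$features, 0)
  expect_identical(
    feature_at(lib, "blank", random_code(ms, frame = "blank"), ms),
    "none"
  )

  pts <- rbind(c(1, 0), c(3, 2), c(0, 4))
  lib <- learn_object(lib, "pen", waypoint_trace(pts, c("f1", "f2", "f3")),
                      ms)
  model <- get_object(lib, "pen")
  expect_length(model$features, 3)
  # storage round-trip: re-deriving each visited location by path
  # integration from the anchor recovers its feature
  for (i in 1:3) {
    loc <- integrate_code(model$anchor, ms, pts[i, ])
    expect_identical(feature_at(lib, "pen", loc, ms),
                     c("f1", "f2", "f3")[i])
  }
})

test_that("revisits are idempotent; conflicting features error", {
  ms <- default_module_set(4)
  set.seed(32)
  # out and back to the same point, same feature both times
  revisit <- exploration_trace(data.frame(
    dx = c(1, 2, -2), dy = c(1, 0, 0),
    feature = c("a", "b", "a")
  ))
  lib <- learn_object(object_library(), "cup", revisit, ms)
  expect_length(get_object(lib, "cup")$features, 2)

  clash <- exploration_trace(data.frame(
    dx = c(1, 2, -2), dy = c(1, 0, 0),
    feature = c("a", "b", "DIFFERENT")
  ))
  err <- expect_error(
    learn_object(object_library(), "cup2", clash, ms),
    class = "cortexgrid_feature_conflict"
  )
  expect_match(conditionMessage(err), "key")
  # force mode overwrites instead
  lib2 <- learn_object(object_library(), "cup3", clash, ms, force = TRUE)
  expect_length(get_object(lib2, "cup3")$features, 2)
})

test_that("learning is frame-consistent across start offsets", {
  ms <- default_module_set(4)
  pts <- rbind(c(0, 0), c(2, 1), c(4, 3))
  labels <- c("rim", "handle", "base")
  set.seed(33)
  lib <- learn_object(object_library(), "first",
                      waypoint_trace(pts, labels), ms)
  # second instance starts its exploration at the handle and walks the
  # object in a different order
  shifted <- exploration_trace(
    data.frame(dx = c(pts[3, 1] - pts[2, 1], pts[1, 1] - pts[3, 1]),
               dy = c(pts[3, 2] - pts[2, 2], pts[1, 2] - pts[3, 2]),
               feature = c(labels[3], labels[1])),
    start_offset = pts[2, ]
  )
  lib <- learn_object(lib, "second", shifted, ms)
  for (i in c(1, 3)) {
    loc1 <- integrate_code(get_object(lib, "first")$anchor, ms, pts[i, ])
    loc2 <- integrate_code(get_object(lib, "second")$anchor, ms, pts[i, ])
    expect_identical(feature_at(lib, "first", loc1, ms),
                     feature_at(lib, "second", loc2, ms))
  }
})

test_that("a hand-built cup-with-logo resolves the logo feature", {
  # two square modules, scales 4 and 5, bins matching their periods;
  # all expected phases below are hand arithmetic
  ms <- sq_ms(c(4, 5), bins_a = c(4L, 5L), bins_b = c(4L, 5L))

  logo_anchor <- lc(0, 0, 0, 0, frame = "logo")
  # logo feature "L" at logo-frame world offset (1, 2):
  # module 1 phase (1/4, 2/4), module 2 phase (1/5, 2/5)
  loc_l <- lc(0.25, 0.5, 0.2, 0.4, frame = "logo")
  cup_anchor <- lc(0.5, 0.5, 0.5, 0.5, frame = "cup")

  lib <- object_library()
  lib <- add_object(lib, object_model("logo", logo_anchor))
  lib <- add_object(lib, object_model("cup", cup_anchor))
  lib <- add_feature(lib, "logo", loc_l, "L", ms)

  # logo origin sits at cup offset (2, -1); the placement displacement is
  # anchor_logo - anchor_cup - lattice(2, -1), by hand:
  #   module 1: (0 - 0.5 - 0.5, 0 - 0.5 + 0.25) mod 1 = (0, 0.75)
  #   module 2: (0 - 0.5 - 0.4, 0 - 0.5 + 0.2) mod 1 = (0.1, 0.7)
  placement <- displacement_code(
    rbind(c(0, 0.75), c(0.1, 0.7)), "cup", "logo"
  )
  lib <- add_component(lib, "cup", "logo", placement)

  # cup offset (3, 1) is co-located with logo offset (1, 2):
  # cup phases by hand: module 1 (0.25, 0.75), module 2 (0.1, 0.7)
  query <- lc(0.25, 0.75, 0.1, 0.7, frame = "cup")
  expect_identical(feature_at(lib, "cup", query, ms), "L")
  # a different cup location misses
  expect_identical(
    feature_at(lib, "cup", lc(0.6, 0.1, 0.3, 0.9, frame = "cup"), ms),
    "none"
  )
  # translations must be explicit: querying with depth 0 stays local
  expect_identical(feature_at(lib, "cup", query, ms, depth_limit = 0L),
                   "none")
})

test_that("every child feature is retrievable through the parent", {
  ms <- default_module_set(4)
  set.seed(34)
  pts <- rbind(c(0, 0), c(1, 2), c(3, 1), c(2, 4))
  labels <- c("w", "x", "y", "z")
  lib <- learn_object(object_library(), "logo",
                      waypoint_trace(pts, labels), ms)
  lib <- add_object(lib, object_model("cup", random_code(ms, "cup")))
  offset <- c(5, -2) # logo origin in cup coordinates
  placement <- displacement_between(
    integrate_code(get_object(lib, "cup")$anchor, ms, offset),
    get_object(lib, "logo")$anchor, ms
  )
  lib <- add_component(lib, "cup", "logo", placement)
  for (i in seq_len(nrow(pts))) {
    parent_loc <- integrate_code(get_object(lib, "cup")$anchor, ms,
                                 offset + pts[i, ])
    expect_identical(feature_at(lib, "cup", parent_loc, ms), labels[i])
  }
})

test_that("components allow multiplicity and bounded recursion", {
  ms <- default_module_set(3)
  set.seed(35)
  lib <- object_library()
  lib <- add_object(lib, object_model("cup", random_code(ms, "cup")))
  lib <- add_object(lib, object_model("logo", random_code(ms, "logo")))

  d1 <- displacement_between(get_object(lib, "cup")$anchor,
                             get_object(lib, "logo")$anchor, ms)
  lib <- add_component(lib, "cup", "logo", d1)
  expect_length(get_object(lib, "cup")$components, 1)
  d2 <- displacement_code(matrix(runif(6), 3, 2), "cup", "logo")
  lib <- add_component(lib, "cup", "logo", d2)
  expect_length(get_object(lib, "cup")$components, 2)

  # recursion is legal: the logo contains the cup
  d3 <- displacement_code(matrix(runif(6), 3, 2), "logo", "cup")
  lib <- add_component(lib, "logo", "cup", d3)
  q <- random_code(ms, frame = "cup")
  expect_identical(feature_at(lib, "cup", q, ms, depth_limit = 3L), "none")

  expect_error(
    add_component(lib, "cup", "logo",
                  displacement_code(matrix(0, 3, 2), "cup", "cup")),
    class = "cortexgrid_frame_mismatch"
  )
  expect_error(add_component(lib, "cup", "mystery", d1),
               class = "cortexgrid_unknown_object")
})

test_that("own features shadow component features deterministically", {
  ms <- default_module_set(3)
  set.seed(36)
  lib <- object_library()
  lib <- add_object(lib, object_model("parent", random_code(ms, "parent")))
  lib <- add_object(lib, object_model("child", random_code(ms, "child")))
  placement <- displacement_between(get_object(lib, "parent")$anchor,
                                    get_object(lib, "child")$anchor, ms)
  lib <- add_component(lib, "parent", "child", placement)
  # the same physical point carries "own" in the parent and "comp" in
  # the child; parent-level observation wins
  loc_p <- integrate_code(get_object(lib, "parent")$anchor, ms, c(1, 1))
  loc_c <- apply_displacement(loc_p, placement, ms)
  lib <- add_feature(lib, "child", loc_c, "comp", ms)
  expect_identical(feature_at(lib, "parent", loc_p, ms), "comp")
  lib <- add_feature(lib, "parent", loc_p, "own", ms)
  expect_identical(feature_at(lib, "parent", loc_p, ms), "own")
})
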