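# Configuration loading, validation and volume distribution.

test_that("default healthy-male configuration loads and validates", {
  m <- load_network(default_config())
  expect_s3_class(m, "network_model")
  expect_equal(m$blood$total_volume, 5700)
  expect_equal(nrow(m$vessels), 24)
  # one root, every leaf has a terminal bed
  expect_equal(sum(is.na(m$vessels$parent_id)), 1)
  leaves <- !(m$vessels$id %in% m$vessels$parent_id)
  expect_true(all(!is.na(m$vessels$terminal_bed_id[leaves])))
  # one capillary/venule/vein in each perfused region
  for (r in c("head", "arms", "upper_abdomen", "lower_abdomen", "legs")) {
    for (k in c("capillary", "venule", "vein")) {
      expect_equal(sum(m$compartments$region == r & m$compartments$kind == k), 1)
    }
  }
})

test_that("structural invariants are enforced with informative errors", {
  raw <- yaml::read_yaml(default_config())
  # a parent chain forming a cycle
  bad <- raw
  bad$vessels[[1]]$parent <- 18      # root now points into the tree
  expect_error(load_network(bad), "root|cycle")
  bad2 <- raw
  bad2$vessels[[3]]$parent <- 4      # brachiocephalic <-> carotid loop
  bad2$vessels[[4]]$parent <- 3
  expect_error(load_network(bad2), "cycle|root")
  # microvascular compartments cannot carry a hydrostatic column
  bad3 <- raw
  bad3$compartments[[1]]$height <- 0.1
  expect_error(load_network(bad3), "anatomical_height")
  # duplicate ids are configuration errors naming the id
  bad4 <- raw
  bad4$vessels[[2]]$id <- 1
  expect_error(load_network(bad4), "duplicate vessel id 1")
  # unresolved downstream breaks the closed loop
  bad5 <- raw
  bad5$compartments[[1]]$downstream <- "nowhere"
  expect_error(load_network(bad5), "nowhere")
  # missing model_version
  bad6 <- raw
  bad6$model_version <- NULL
  expect_error(load_network(bad6), "model_version")
})

test_that("blood volume distribution conserves the total exactly", {
  fr <- c(a = 0.3, b = 0.45, c = 0.25)
  v <- distribute_blood_volume(5700, fr)
  expect_identical(sum(v), 5700)
  # degenerate distribution
  v2 <- distribute_blood_volume(5700, c(a = 1, b = 0, c = 0))
  expect_equal(unname(v2), c(5700, 0, 0))
  # linearity in the total
  expect_equal(distribute_blood_volume(11400, fr), 2 * v)
  # awkward fractions still sum exactly
  fr3 <- rep(1 / 7, 7)
  names(fr3) <- letters[1:7]
  expect_identical(sum(distribute_blood_volume(1234.567, fr3)), 1234.567)
  expect_error(distribute_blood_volume(5700, c(a = 0.5, b = 0.4)),
               "fractions")
})

test_that("fixture networks are well formed", {
  fx <- fixture_networks()
  expect_equal(fx$single_vessel$n_vessels, 1)
  expect_equal(fx$single_vessel$n_compartments, 0)
  expect_identical(fx$symmetric_bifurcation$n_children, 2)
  expect_s3_class(fx$minimal_closed_loop, "network_model")
  expect_equal(nrow(fx$minimal_closed_loop$vessels), 1)
})

test_that("serialization round-trips all fields exactly", {
  m <- load_network(default_config())
  path <- tempfile(fileext = ".json")
  serialize_network(m, path)
  m2 <- load_network(path)
  expect_identical(m$vessels, m2$vessels)
  expect_identical(m$compartments, m2$compartments)
  expect_identical(m$blood$total_volume, m2$blood$total_volume)
  expect_identical(m$regulation, m2$regulation)
  unlink(path)
})
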