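test_that("wide community tables are read and filtered", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(site = c("a", "b", "c"),
                   lon = c(-50, -51, -52), lat = c(-20, -21, -22),
                   A = c(1, 1, 1), B = c(1, 0, 1), C = c(0, 0, 1))
  write.csv(df, path, row.names = FALSE)
  cm <- suppressMessages(read_community_table(path))
  # site b has a single species and must be dropped
  expect_setequal(cm$site_ids, c("a", "c"))
  expect_equal(attr(cm, "dropped_sites"), "b")
  expect_equal(unname(cm$incidence["c", ]), c(1L, 1L, 1L))
})

test_that("long community tables build the incidence matrix", {
  path <- withr::local_tempfile(fileext = ".csv")
  recs <- expand.grid(site = c("s1", "s2", "s3"),
                      species = c("A", "B", "C", "D"))
  recs$lon <- -50 - as.integer(factor(recs$site))
  recs$lat <- -20
  write.csv(recs, path, row.names = FALSE)
  cm <- read_community_table(path)
  expect_equal(dim(cm$incidence), c(3L, 4L))
  expect_true(all(cm$incidence == 1L))

  # duplicated records are a validation error naming the offender
  write.csv(rbind(recs, recs[1, ]), path, row.names = FALSE)
  expect_error(read_community_table(path), "duplicate")
})

test_that("missing coordinate columns are a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(site = "a", A = 1, B = 1), path, row.names = FALSE)
  expect_error(read_community_table(path), "coordinate")
})

test_that("site filtering is idempotent", {
  set.seed(42)
  inc <- matrix(rbinom(60, 1, 0.4), 10, 6,
                dimnames = list(paste0("s", 1:10), paste0("sp", 1:6)))
  coords <- cbind(runif(10, -55, -35), runif(10, -30, -5))
  coords[3, 1] <- NA
  rownames(coords) <- rownames(inc)
  f1 <- filter_sites(inc, coords)
  f2 <- filter_sites(f1$incidence, f1$coords)
  expect_identical(f1$incidence, f2$incidence)
  expect_length(f2$dropped, 0L)
  expect_true("s3" %in% f1$dropped)
})

test_that("trees must be rooted with branch lengths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tr <- read_tree(path)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(ape::node.depth.edgelength(tr)[1], 2)  # root-to-A distance

  writeLines("((A,B),C);", path)
  expect_error(read_tree(path), "branch length")
})

test_that("alignment restricts to shared ids and reports the dropped", {
  cm <- tiny_cm()
  tt <- data.frame(development_type = c("direct", "larval", "larval",
                                        "larval", "direct"),
                   row.names = c("A", "B", "C", "D", "extra"))
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  env <- data.frame(BIO4 = rnorm(4), row.names = c("s1", "s2", "s3", "s4"))
  al <- align_inputs(cm, tt, tree, env)
  expect_identical(al$cm$species_ids, colnames(al$cm$incidence))
  expect_setequal(al$cm$species_ids, c("A", "B", "C", "D"))
  expect_equal(al$dropped$species_tt, "extra")
  expect_identical(rownames(al$env), al$cm$site_ids)

  # identical id sets pass through unchanged
  al2 <- align_inputs(cm, tt[1:4, , drop = FALSE], tree, env)
  expect_equal(al2$cm$incidence, cm$incidence)

  # a community species missing from the tree is dropped with a report,
  # and an empty intersection is an error
  tr2 <- ape::drop.tip(tree, "D")
  al3 <- align_inputs(cm, tt, tr2, env)
  expect_false("D" %in% al3$cm$species_ids)
  expect_error(align_inputs(cm, tt[5, , drop = FALSE], tree, env),
               "no species")
})

test_that("trait tables enforce the fixed vocabulary", {
  tt <- data.frame(development_type = c("direct", "larval"),
                   body_length = c(20, 35),
                   row.names = c("A", "B"))
  expect_s3_class(validate_trait_table(tt)$development_type, "factor")
  tt$development_type <- c("direct", "tadpole")
  expect_error(validate_trait_table(tt), "invalid development_type")
  tt$development_type <- c("direct", NA)
  expect_error(validate_trait_table(tt), "missing")
  tt$development_type <- c("direct", "larval")
  tt$body_length <- c(-1, 10)
  expect_error(validate_trait_table(tt), "positive")
})

test_that("scenario files round-trip through the readers", {
  sc <- simulate_scenario(scenario_config(n_species = 30, n_sites = 15,
                                          dd_fraction = 0.2,
                                          dd_clade_count = 1L, seed = 5))
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  cm <- read_community_table(file.path(dir, "community.csv"))
  expect_equal(sort(cm$site_ids), sort(sc$cm$site_ids))
  # species never observed in any community are absent from the long file
  expect_true(all(cm$species_ids %in% sc$cm$species_ids))
  expect_equal(cm$incidence[sc$cm$site_ids, cm$species_ids],
               sc$cm$incidence[, cm$species_ids])
  tt <- read_trait_table(file.path(dir, "traits.csv"))
  expect_equal(sum(is.na(tt$head_width)), sum(is.na(sc$traits$head_width)))
  env <- read_env_table(file.path(dir, "env.csv"))
  expect_equal(as.matrix(env[rownames(sc$env), ]),
               as.matrix(sc$env), tolerance = 1e-12)
})
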