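test_that("fixture clusters parse with the expected module organization", {
  akae <- read_cluster(fixture("akaeolide_cluster.txt"))
  expect_s3_class(akae, "pks_cluster")
  expect_length(akae$modules, 8L)  # one loading + seven extension
  expect_true(akae$modules[[1]]$loading)
  expect_length(extension_modules <- akae$modules[-1], 7L)
  expect_false(any(vapply(extension_modules, `[[`, logical(1), "loading")))

  lorn <- read_cluster(fixture("lorneic_cluster.txt"))
  expect_length(lorn$modules, 8L)

  # silenced DH domains are read back as inactive
  dh3 <- Filter(function(d) d$kind == "DH", akae$modules[[4]]$domains)[[1]]
  dh6 <- Filter(function(d) d$kind == "DH", akae$modules[[7]]$domains)[[1]]
  expect_false(dh3$active)
  expect_false(dh6$active)
})

test_that("invariant violations are rejected with validation errors", {
  # two loading modules
  two_loading <- c("cluster bad", "module 0 loading", "domain AT signature=HAFH",
                   "module 1 loading", "domain AT signature=HAFH")
  path <- withr::local_tempfile(lines = two_loading)
  expect_error(read_cluster(path), class = "pks_validation_error")

  # empty module list
  path2 <- withr::local_tempfile(lines = "cluster empty")
  expect_error(read_cluster(path2), class = "pks_validation_error")

  # duplicate module index
  dup <- c("cluster dup", "module 0 loading", "domain AT signature=HAFH",
           "module 1", "domain KS", "domain AT signature=HAFH",
           "module 1", "domain KS", "domain AT signature=HAFH")
  path3 <- withr::local_tempfile(lines = dup)
  expect_error(read_cluster(path3), class = "pks_validation_error")

  # domain-level invariants
  expect_error(domain_spec("AT", signature = ""), class = "pks_validation_error")
  expect_error(domain_spec("DH", kr_fingerprint = "B1"), class = "pks_validation_error")
  expect_error(domain_spec("XX"), class = "pks_validation_error")
  # extension module without KS
  expect_error(module_spec(1L, list(domain_spec("AT", signature = "HAFH"))),
               class = "pks_validation_error")
  # missing file
  expect_error(read_cluster(file.path(tempdir(), "nope.txt")), class = "pks_io_error")
})

test_that("write/read round trips are identities, flags included", {
  akae <- read_cluster(fixture("akaeolide_cluster.txt"))
  path <- withr::local_tempfile()
  write_cluster(akae, path)
  expect_equal(read_cluster(path), akae)

  for (seed in 1:8) {
    sim <- generate_cluster(simulation_config(seed = seed,
                                              n_extension_modules = 3L))
    p <- withr::local_tempfile()
    write_cluster(sim$cluster, p)
    back <- read_cluster(p)
    expect_equal(back, sim$cluster)
  }
})

test_that("reductive profile census matches the annotated clusters", {
  akae <- read_cluster(fixture("akaeolide_cluster.txt"))
  annotated <- count_reductive_profiles(akae, active_only = FALSE)
  expect_equal(annotated[["DH+KR"]], 4L)
  expect_equal(annotated[["DH+ER+KR"]], 1L)
  expect_equal(sum(annotated), 7L)

  # with the silent DHs discounted, two modules fall back to KR-only
  active <- count_reductive_profiles(akae)
  expect_equal(active[["DH+KR"]], 2L)
  expect_equal(active[["KR"]], 2L)

  lorn <- read_cluster(fixture("lorneic_cluster.txt"))
  lp <- count_reductive_profiles(lorn, active_only = FALSE)
  expect_equal(lp[["DH+ER+KR"]], 3L)
  expect_equal(lp[["DH+KR"]], 4L)

  # a cluster with no reductive domains is all 'none'
  bare <- cluster_spec("bare", list(
    module_spec(0L, list(domain_spec("AT", signature = "HAFH")), loading = TRUE),
    module_spec(1L, list(domain_spec("KS"), domain_spec("AT", signature = "HAFH"))),
    module_spec(2L, list(domain_spec("KS"), domain_spec("AT", signature = "HAFH")))))
  expect_equal(count_reductive_profiles(bare)[["none"]], 2L)

  # census totals always equal the extension-module count
  for (seed in 1:10) {
    cl <- generate_cluster(simulation_config(seed = seed,
                                             n_extension_modules = 5L))$cluster
    expect_equal(sum(count_reductive_profiles(cl, active_only = FALSE)), 5L)
    expect_equal(sum(count_reductive_profiles(cl)), 5L)
  }
})

test_that("screen_clusters shortlists by module count", {
  akae <- read_cluster(fixture("akaeolide_cluster.txt"))
  lorn <- read_cluster(fixture("lorneic_cluster.txt"))
  small <- generate_cluster(simulation_config(seed = 3L,
                                              n_extension_modules = 4L))$cluster
  hits <- screen_clusters(list(akae, lorn, small), 8L)
  expect_setequal(hits, c("akaeolide_bgc", "lorneic_bgc"))
  expect_identical(screen_clusters(list(), 8L), character(0))
  expect_identical(screen_clusters(list(akae, lorn, small), 0L), character(0))
})
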