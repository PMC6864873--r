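test_that("fitted descriptor statistics equal a brute-force tally", {
  ds <- toy_dataset()
  model <- ddipass(ds)

  # independent tally straight from per-pair PoSMNA sets
  feats <- lapply(seq_len(nrow(ds$pairs)), function(i)
    posmna_pair(ds$drugs[[ds$pairs$drug_a[i]]],
                ds$drugs[[ds$pairs$drug_b[i]]])$descriptors)
  tally_n <- table(unlist(feats))
  expect_identical(model$n_pairs, nrow(ds$pairs))
  expect_identical(sum(model$class_counts), nrow(ds$pairs))
  for (d in names(tally_n)) {
    k <- match(d, model$vocab)
    expect_identical(model$d_n[k], as.integer(tally_n[[d]]))
    for (c in 1:5) {
      in_c <- which(ds$pairs$orca_class == c)
      expect_identical(model$d_nc[k, c],
                       sum(vapply(feats[in_c], function(f) d %in% f, logical(1))))
    }
    expect_true(model$d_nc[k, ds$pairs$orca_class[1]] <= model$d_n[k])
  }
})

test_that("fitting is invariant to the order of training pairs", {
  ds <- toy_dataset()
  m1 <- ddipass(ds)
  ds2 <- ds
  set.seed(5)
  perm <- sample.int(nrow(ds$pairs))
  ds2$pairs <- ds$pairs[perm, ]
  m2 <- ddipass(ds2)
  expect_identical(m1$vocab, m2$vocab)
  expect_identical(m1$d_n, m2$d_n)
  expect_identical(m1$d_nc, m2$d_nc)
  q <- data.frame(drug_a = "methane", drug_b = "ethanol")
  expect_identical(predict(m1, q), predict(m2, q))
})

test_that("raw scores follow the arcsine-mean closed form", {
  # single known descriptor seen k times, all in class 1
  priors <- c(0.4, 0.3, 0.1, 0.1, 0.1)
  prev <- -Inf
  for (k in c(1, 3, 10, 100)) {
    dnc <- matrix(0L, 1L, 5L); dnc[1L, 1L] <- k
    s <- ddipass:::.pass_raw_scores(k, dnc, priors, alpha = 1)
    expect_equal(s[1L], 2 * (k + priors[1L]) / (k + 1) - 1)
    expect_gt(s[1L], prev)    # approaches 1 monotonically
    prev <- s[1L]
  }
  # no known descriptor: prior fallback for every class
  s0 <- ddipass:::.pass_raw_scores(integer(0),
                                   matrix(0L, 0L, 5L), priors, alpha = 1)
  expect_equal(s0, 2 * priors - 1)
})

test_that("a descriptor's class probability never decreases with support", {
  ds <- toy_dataset()
  m1 <- ddipass(ds)
  # duplicate the class-1 pair's structures under fresh IDs and add the pair
  ds2 <- ds
  ds2$drugs$methane2 <- ds$drugs$methane; ds2$drugs$methane2$id <- "methane2"
  ds2$drugs$ethane2 <- ds$drugs$ethane;   ds2$drugs$ethane2$id <- "ethane2"
  ds2$pairs <- rbind(ds2$pairs, data.frame(drug_a = "ethane2", drug_b = "methane2",
                                           orca_class = 1L))
  ds2 <- ddi_dataset(ds2$drugs, ds2$pairs)
  m2 <- ddipass(ds2)
  d <- posmna_pair(ds$drugs$methane, ds$drugs$ethane)$descriptors
  p1 <- coef(m1)[d, "class1"]
  p2 <- coef(m2)[d, "class1"]
  expect_true(all(p2 >= p1))
})

test_that("a pair supported by a single class ranks that class first", {
  drugs <- list(methane = mg_methane(), ethane = mg_ethane(),
                benzene = mg_benzene(), cyclopentane = mg_cyclopentane())
  ds <- ddi_dataset(drugs, data.frame(
    drug_a = c("ethane", "benzene"), drug_b = c("methane", "cyclopentane"),
    orca_class = c(1L, 5L)))
  m <- ddipass(ds)
  pred <- predict(m, data.frame(drug_a = "methane", drug_b = "ethane"))
  expect_identical(pred$orca_class[1L], 1L)   # rows sorted by pa - pi
  expect_true(all(pred$pa >= 0 & pred$pa <= 1))
  expect_true(all(pred$pi >= 0 & pred$pi <= 1))
})

test_that("predictions are symmetric under swapping the two drugs", {
  ds <- simulate_ddi_dataset(30, 60, seed = 21)
  m <- ddipass(ds)
  ids <- names(ds$drugs)
  set.seed(77)
  for (r in 1:10) {
    ij <- sample(ids, 2L)
    p1 <- predict(m, data.frame(drug_a = ij[1L], drug_b = ij[2L]))
    p2 <- predict(m, data.frame(drug_a = ij[2L], drug_b = ij[1L]))
    expect_identical(p1[, c("orca_class", "score", "pa", "pi")],
                     p2[, c("orca_class", "score", "pa", "pi")])
  }
})

test_that("Pa of a class with no training pairs is zero", {
  drugs <- list(methane = mg_methane(), ethane = mg_ethane(),
                benzene = mg_benzene())
  ds <- ddi_dataset(drugs, data.frame(
    drug_a = c("ethane", "benzene"), drug_b = c("methane", "methane"),
    orca_class = c(1L, 3L)))
  m <- ddipass(ds)
  pred <- predict(m, data.frame(drug_a = "ethane", drug_b = "benzene"))
  expect_identical(pred$pa[match(c(2L, 4L, 5L), pred$orca_class)], c(0, 0, 0))
})

test_that("Pa/Pi depend on raw scores only through their ranks", {
  ds <- toy_dataset()
  m <- ddipass(ds)
  q <- data.frame(drug_a = "benzene", drug_b = "ethanol")
  base <- predict(m, q)
  m3 <- m
  m3$training_scores <- m$training_scores^3   # strictly increasing on [-1, 1]
  desc <- posmna_pair(ds$drugs$benzene, ds$drugs$ethanol)$descriptors
  ki <- match(desc, m$vocab); ki <- ki[!is.na(ki)]
  raw <- ddipass:::.pass_raw_scores(m$d_n[ki], m$d_nc[ki, , drop = FALSE],
                                    m$class_counts / m$n_pairs, m$alpha)
  cal <- ddipass:::.calibrate_pa_pi(m, raw)
  cal3 <- ddipass:::.calibrate_pa_pi(m3, raw^3)
  expect_equal(cal3$pa, cal$pa)
  expect_equal(cal3$pi, cal$pi)
  expect_equal(base$pa, cal$pa[base$orca_class])
})

test_that("models survive a JSON round-trip bit-identically", {
  ds <- simulate_ddi_dataset(25, 50, seed = 31)
  m <- ddipass(ds)
  f <- tempfile(fileext = ".json")
  write_ddipass(m, f)
  m2 <- read_ddipass(f)
  ids <- names(ds$drugs)
  set.seed(123)
  for (r in 1:10) {
    ij <- sample(ids, 2L)
    q <- data.frame(drug_a = ij[1L], drug_b = ij[2L])
    expect_identical(predict(m, q), predict(m2, q))
  }

  writeLines("{ not json", f)
  expect_error(read_ddipass(f), "cannot read model file")
  jsonlite::write_json(list(format = "something-else/9"), f, auto_unbox = TRUE)
  expect_error(read_ddipass(f), "unsupported format version")
})

test_that("unknown drugs can be scored by supplying their structures", {
  ds <- toy_dataset()
  m <- ddipass(ds)
  expect_error(predict(m, data.frame(drug_a = "methane", drug_b = "propane")),
               "unknown drug")
  pred <- predict(m, data.frame(drug_a = "methane", drug_b = "propane"),
                  structures = list(propane = mg_propane()))
  expect_identical(nrow(pred), 5L)
})
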