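test_that("posterior probabilities classify into confidence bands", {
  expect_equal(classifyTM(0.9), "high")
  expect_equal(classifyTM(0.5), "potential")
  expect_equal(classifyTM(0.01), "soluble")
  # band edges: 0.75 and 0.037 both fall in the potential band
  expect_equal(classifyTM(c(0.75, 0.037)), c("potential", "potential"))
  expect_equal(classifyTM(0.0369), "soluble")
  expect_error(classifyTM(1.2), "0, 1")
  # monotone in the posterior
  rank <- c(soluble = 1L, potential = 2L, high = 3L)
  p <- sort(stats::runif(50))
  expect_true(all(diff(rank[classifyTM(p)]) >= 0))
})

test_that("region building merges annotation and prediction intervals", {
  # no TMs -> single soluble region
  t0 <- buildRegions("P", 80)
  expect_equal(t0@regions$type, "soluble")
  expect_equal(c(t0@regions$start, t0@regions$end), c(1L, 80L))

  # one TM [10,30] in length 50
  t1 <- buildRegions("P", 50, annotated = data.frame(start = 10, end = 30))
  expect_equal(t1@regions$start, c(1L, 10L, 31L))
  expect_equal(t1@regions$end, c(9L, 30L, 50L))
  expect_equal(t1@regions$type, c("soluble", "tm", "soluble"))

  # overlapping predicted [12,34] + annotated [15,36] -> merged TM [12,36]
  t2 <- buildRegions("P", 60,
                     predicted = data.frame(start = 12, end = 34,
                                            posterior = 0.9),
                     annotated = data.frame(start = 15, end = 36))
  tm <- t2@regions[t2@regions$type == "tm", ]
  expect_equal(c(tm$start, tm$end), c(12L, 36L))
  expect_equal(tm$confidence, "annotated")  # annotation outranks prediction

  # soluble-class predictions never become TM segments
  t3 <- buildRegions("P", 60,
                     predicted = data.frame(start = c(10, 40),
                                            end = c(20, 50),
                                            posterior = c(0.5, 0.01)))
  expect_equal(sum(t3@regions$type == "tm"), 1L)
  expect_equal(t3@regions$confidence[t3@regions$type == "tm"], "potential")
  expect_error(buildRegions("P", 30, annotated = data.frame(start = 10,
                                                            end = 40)),
               "outside")
})

test_that("merged regions equal an interval-union oracle on random inputs", {
  set.seed(47)
  for (rep in 1:30) {
    len <- 200L
    n <- sample(1:4, 1)
    starts <- sort(sample(1:180, n))
    ends <- pmin(starts + sample(5:30, n, TRUE), len)
    top <- buildRegions("P", len,
                        annotated = data.frame(start = starts, end = ends))
    covered <- rep(FALSE, len)
    for (i in seq_len(n)) covered[starts[i]:ends[i]] <- TRUE
    oracle_tm <- rle(covered)
    pos <- cumsum(c(1L, oracle_tm$lengths))
    o_start <- pos[-length(pos)][oracle_tm$values]
    o_end <- (pos[-1L] - 1L)[oracle_tm$values]
    tm <- top@regions[top@regions$type == "tm", ]
    expect_equal(tm$start, o_start)
    expect_equal(tm$end, o_end)
    # regions tile [1, len] -- validity already enforces it, spot-check
    expect_equal(sum(top@regions$end - top@regions$start + 1L), len)
  }
})

test_that("orientation propagates anchors by side alternation", {
  model <- defaultMitoModel()
  # even TM count, C-terminus anchored IMS -> N-terminus IMS too
  even <- buildRegions("P", 120,
                       annotated = data.frame(start = c(30, 70),
                                              end = c(50, 90)))
  o <- orientTopology(even, data.frame(region = 3L, compartment = "IMS"),
                      membrane = "IMM", model = model)
  sol <- solubleRegions(o)
  expect_equal(o@orientation, "full")
  expect_equal(sol$compartment, c("IMS", "matrix", "IMS"))

  # without knowing the membrane, only even-parity regions resolve
  o2 <- orientTopology(even, data.frame(region = 3L, compartment = "IMS"),
                       model = model)
  expect_equal(o2@orientation, "partial")
  expect_equal(solubleRegions(o2)$compartment, c("IMS", NA, "IMS"))

  # 1 TM OMM protein, N-terminus cytosol -> C-terminus IMS
  one <- buildRegions("P", 80,
                      annotated = data.frame(start = 35, end = 55))
  o3 <- orientTopology(one, data.frame(region = 1L, compartment = "cytosol"),
                       membrane = "OMM", model = model)
  expect_equal(solubleRegions(o3)$compartment, c("cytosol", "IMS"))

  # two-sided anchors identify the membrane on their own
  o4 <- orientTopology(even, data.frame(region = 1:2,
                                        compartment = c("IMS", "matrix")),
                       model = model)
  expect_equal(o4@membrane, "IMM")
  expect_equal(o4@orientation, "full")

  # conflicting anchors flag the topology
  o5 <- orientTopology(even, data.frame(region = c(1L, 2L),
                                        compartment = c("IMS", "IMS")),
                       membrane = "IMM", model = model)
  expect_equal(o5@orientation, "inconsistent")
  expect_error(orientTopology(even,
                              data.frame(region = 1L,
                                         compartment = "cytosol"),
                              membrane = "IMM", model = model),
               "not adjacent")
})

test_that("orientation matches exhaustive enumeration and ignores anchor order", {
  model <- defaultMitoModel()
  set.seed(53)
  for (rep in 1:40) {
    n_tm <- sample(1:5, 1)
    membrane <- sample(membraneCompartments(model), 1)
    sides <- membraneSides(model, membrane)
    tm <- data.frame(start = (1:n_tm) * 40 - 19, end = (1:n_tm) * 40)
    top <- buildRegions("P", max(tm$end) + 25L, annotated = tm)
    k <- n_tm + 1L
    truth_start <- sample(sides, 1)
    truth <- rep(c(truth_start, setdiff(sides, truth_start)),
                 length.out = k)
    n_anchor <- sample(1:k, 1)
    regs <- sort(sample(seq_len(k), n_anchor))
    anchors <- data.frame(region = regs, compartment = truth[regs])
    o <- orientTopology(top, anchors, membrane = membrane, model = model)
    oracle <- oracleOrient(k, anchors, sides)
    expect_length(oracle, 1)
    expect_equal(solubleRegions(o)$compartment, oracle[[1]])
    # anchor order must not matter
    o2 <- orientTopology(top, anchors[rev(seq_len(nrow(anchors))), ],
                         membrane = membrane, model = model)
    expect_equal(solubleRegions(o2)$compartment,
                 solubleRegions(o)$compartment)
  }
})

test_that("termini share a side exactly when the TM count is even", {
  set.seed(59)
  org <- generateOrganelle(1000, 0, 1, seed = 59)
  for (top in org@topologies) {
    sol <- solubleRegions(top)
    nterm <- sol$compartment[1L]
    cterm <- sol$compartment[nrow(sol)]
    if (tmCount(top) %% 2L == 0L) expect_equal(cterm, nterm)
    else expect_true(cterm != nterm)
  }
})
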