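test_that("the acceptor angle is the planar angle at the acceptor", {
  d <- c(0, 0, 3); a <- c(0, 0, 0)
  ant <- c(sin(pi / 3) * 3, 0, -cos(pi / 3) * 3)
  expect_equal(acceptorAngle(d, a, ant), 120, tolerance = 1e-9)
  expect_equal(acceptorAngle(c(0, 0, 3), a, c(0, 0, -2)), 180)
  expect_error(acceptorAngle(d, a, a), "zero-length")
})

test_that("each classification window fires strictly inside and not at its boundary", {
  crit <- bondCriteria()
  pairAt <- function(d, cov = 0.8, vdw = 1.7, ...) {
    a <- mkatom(0, 0, 0, cov, vdw, ...)
    b <- mkatom(d, 0, 0, cov, vdw)
    classifyAtomPair(a, b, crit)
  }
  # covalent: d < covsum (= 1.6)
  expect_equal(pairAt(1.5)$type, "covalent")
  expect_equal(pairAt(1.6)$type, "none")               # boundary-equal
  # electrostatic window (covsum, vdwsum) = (1.6, 3.3), opposite charges
  cp <- function(d, qa, qb)
    classifyAtomPair(mkatom(0, 0, 0, 0.8, 1.6, charge = qa),
                     mkatom(d, 0, 0, 0.8, 1.7, charge = qb), crit)
  expect_equal(cp(2.5, 1, -1)$type, "electrostatic")
  expect_equal(cp(2.5, 1, 1)$type, "none")             # like charges
  expect_equal(cp(1.6, 1, -1)$type, "none")            # lower boundary
  expect_equal(cp(3.3, 1, -1)$type, "none")            # upper boundary
  # vdw window (vdwsum, vdwsum + 1.5) = (3.4, 4.9)
  expect_equal(pairAt(4.0)$type, "vdw")
  expect_equal(pairAt(3.4)$type, "none")
  expect_equal(pairAt(4.9)$type, "none")
  expect_equal(pairAt(5.0)$type, "none")
})

test_that("hydrogen bonds need donor/acceptor flags, 3.6 A and the angle window", {
  crit <- bondCriteria()
  ant <- c(1.23, 0, 0)
  hb <- function(angleDeg, d = 3.0) {
    donor <- mkatom(d * cos(angleDeg * pi / 180),
                    d * sin(angleDeg * pi / 180), 0, 0.71, 1.55,
                    donor = 1)
    acc <- mkatom(0, 0, 0, 0.66, 1.52, acceptor = 1)
    classifyAtomPair(donor, acc, crit, antecedentB = ant)
  }
  r <- hb(120)
  expect_equal(r$type, "hydrogen")
  expect_equal(r$distance, 3.0)
  expect_equal(r$angle, 120, tolerance = 1e-9)
  expect_equal(hb(150)$type, "none")   # angle out, d < vdwsum -> nothing
  expect_equal(hb(89)$type, "none")
  expect_equal(hb(90)$type, "hydrogen")   # inclusive ends
  expect_equal(hb(140)$type, "hydrogen")
  # beyond the D-A cutoff the pair falls through to the vdw window
  expect_equal(hb(120, d = 3.65)$type, "vdw")

  # a missing antecedent skips the rule with a warning, not an abort
  donor <- mkatom(-1.5, 2.5981, 0, 0.71, 1.55, donor = 1)
  acc <- mkatom(0, 0, 0, 0.66, 1.52, acceptor = 1)
  expect_warning(r2 <- classifyAtomPair(donor, acc, crit), "antecedent")
  expect_equal(r2$type, "none")
})

test_that("electrostatic precedence beats hydrogen for charged donor/acceptor pairs", {
  crit <- bondCriteria()
  donor <- mkatom(0, 0, 2.2, 0.71, 1.55, charge = 1, donor = 1)
  acc <- mkatom(0, 0, 0, 0.66, 1.52, charge = -1, acceptor = 1)
  r <- classifyAtomPair(donor, acc, crit, antecedentB = c(1.23, 0, 1.1))
  expect_equal(r$type, "electrostatic")
})

test_that("classification is symmetric in argument order", {
  crit <- bondCriteria()
  set.seed(11)
  for (i in 1:200) {
    cova <- runif(1, 0.3, 1.3); covb <- runif(1, 0.3, 1.3)
    a <- mkatom(0, 0, 0, cova, cova + runif(1, 0.2, 1.2),
                charge = sample(-1:1, 1), donor = rbinom(1, 1, 0.5),
                acceptor = rbinom(1, 1, 0.5))
    b <- mkatom(runif(1, 0.5, 6), runif(1, -2, 2), runif(1, -2, 2),
                covb, covb + runif(1, 0.2, 1.2),
                charge = sample(-1:1, 1), donor = rbinom(1, 1, 0.5),
                acceptor = rbinom(1, 1, 0.5))
    antA <- c(a$x, a$y, a$z) + runif(3, -1, 1)
    antB <- c(b$x, b$y, b$z) + runif(3, -1, 1)
    r1 <- suppressWarnings(classifyAtomPair(a, b, crit, antA, antB))
    r2 <- suppressWarnings(classifyAtomPair(b, a, crit, antB, antA))
    expect_identical(r1$type, r2$type)
    expect_equal(r1$angle, r2$angle)
  }
})

test_that("bond enumeration equals the exhaustive all-pairs scan", {
  a <- atomRow(1, "CB", "ALA", "A", 1, 0, 0, 0, "C")
  b <- atomRow(2, "CB", "ALA", "B", 1, 4.0, 0, 0, "C")
  one <- detectBonds(a, b)
  expect_equal(nrow(one), 1L)
  expect_equal(one$bond_type, "vdw")
  expect_equal(one$distance, 4.0)

  far <- atomRow(2, "CB", "ALA", "B", 1, 10, 0, 0, "C")
  expect_equal(nrow(detectBonds(a, far)), 0L)
  expect_equal(nrow(detectBonds(a[0, ], b)), 0L)

  for (s in c(5, 17)) {
    f <- randomFixture(50, s)
    at <- atoms(f$structure)
    A <- at[at$chain == "A", ]; B <- at[at$chain == "B", ]
    g <- suppressWarnings(detectBonds(A, B, method = "grid"))
    e <- suppressWarnings(detectBonds(A, B, method = "exhaustive"))
    expect_identical(g, e)
  }
})

test_that("hydrogen atoms and unparameterized atoms are excluded with a warning", {
  a <- rbind(atomRow(1, "CB", "ALA", "A", 1, 0, 0, 0, "C"),
             atomRow(2, "H", "ALA", "A", 1, 0.5, 0, 0, "H"))
  b <- rbind(atomRow(3, "CB", "ALA", "B", 1, 4.0, 0, 0, "C"),
             atomRow(4, "Q1", "XYZ", "B", 2, 4.0, 1, 0, "XX"))
  expect_warning(bonds <- detectBonds(a, b), "unparameterized")
  expect_equal(nrow(bonds), 1L)     # only the heavy, parameterized pair
})
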