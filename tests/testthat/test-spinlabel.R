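test_that("PDB structures round-trip and parse defensively", {
  st <- helix_dimer_fixture(16, separation = 2.5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, f)
  st2 <- read_pdb(f)
  expect_identical(nrow(st2$atoms), nrow(st$atoms))
  expect_lt(max(abs(as.matrix(st$atoms[, c("x", "y", "z")]) -
                      as.matrix(st2$atoms[, c("x", "y", "z")]))), 1e-3)
  # two MODELs: only the first is kept
  lines <- readLines(f)
  body <- grep("^ATOM", lines, value = TRUE)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", body, "ENDMDL",
               "MODEL     2", body, "ENDMDL", "END"), f2)
  expect_identical(nrow(read_pdb(f2)$atoms), nrow(st$atoms))
  # malformed coordinates carry a line number
  badl <- body
  substr(badl[3], 31, 38) <- "  xx.xxx"
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(badl, f3)
  expect_error(read_pdb(f3), "line 3")
  expect_error(read_pdb("JUNK\nEND"), "no ATOM")
})

test_that("exposed sites reach the full rotamer ensemble under the clash rule", {
  st <- helix_dimer_fixture(20, separation = 4)
  ens <- attach_rotamers(st, list(chain = "A", resno = 10), seed = 1)
  expect_identical(ens$accepted, 200L)
  expect_true(all(ens$clashes <= 5))
  # independent clash recount: brute-force all-pairs distances
  env <- st$atoms[!(st$atoms$chain == "A" & st$atoms$resno == 10), ]
  exyz <- as.matrix(env[, c("x", "y", "z")])
  recount <- vapply(ens$coords, function(sc) {
    d2 <- outer(rowSums(sc^2), rowSums(exyz^2), `+`) - 2 * sc %*% t(exyz)
    sum(d2 < 2.5^2)
  }, numeric(1))
  expect_identical(as.integer(recount), as.integer(ens$clashes))
  # label extension is bounded by the template geometry
  cb <- unlist(st$atoms[st$atoms$chain == "A" & st$atoms$resno == 10 &
                          st$atoms$elety == "CB", c("x", "y", "z")])
  expect_lt(max(sqrt(rowSums(sweep(ens$midpoints, 2, cb)^2))), 12)
  # determinism
  ens2 <- attach_rotamers(st, list(chain = "A", resno = 10), seed = 1)
  expect_identical(ens$midpoints, ens2$midpoints)
  ens3 <- attach_rotamers(st, list(chain = "A", resno = 10), seed = 2)
  expect_false(identical(ens$midpoints, ens3$midpoints))
})

test_that("tight restraints enforce a zero-clash rule", {
  st <- helix_dimer_fixture(20, separation = 4)
  ens <- attach_rotamers(st, list(chain = "A", resno = 10), vdw = "tight",
                         mode = "quick", seed = 1)
  expect_true(all(ens$clashes == 0))
  expect_identical(ens$cutoff, 3.4)
})

test_that("pair distributions follow a translation oracle and symmetry", {
  st <- helix_dimer_fixture(20, separation = 5)  # 50 A apart
  ensA <- attach_rotamers(st, list(chain = "A", resno = 10), seed = 1)
  # same rotamers translated by 50 A: identical internal geometry
  ensB <- ensA
  ensB$midpoints[, 1] <- ensB$midpoints[, 1] + 50
  pd <- pair_distance_distribution(ensA, ensB)
  expect_lt(abs(pd$mean_nm - 5.0), 0.15)
  pd_swap <- pair_distance_distribution(ensB, ensA)
  expect_equal(pd$distribution$P, pd_swap$distribution$P)
  expect_equal(pd$mean_nm, pd_swap$mean_nm)
  # single-rotamer ensembles give a single occupied bin
  e1 <- ensA; e1$midpoints <- ensA$midpoints[1, , drop = FALSE]
  e2 <- ensB; e2$midpoints <- ensB$midpoints[1, , drop = FALSE]
  pd1 <- pair_distance_distribution(e1, e2)
  expect_identical(sum(pd1$distribution$P > 0), 1L)
  d <- sqrt(sum((e1$midpoints - e2$midpoints)^2)) / 10
  expect_lt(abs(pd1$distribution$r[which.max(pd1$distribution$P)] - d), 0.05)
})

test_that("cross-chain site pairs report the construction distance", {
  st <- helix_dimer_fixture(20, separation = 3)
  pred <- predict_pair(st, list(chain = "A", resno = 10),
                       list(chain = "B", resno = 10), seed = 1)
  expect_lt(abs(pred$mean_nm - 3.0), 0.3)
  expect_gt(pred$sd_nm, 0.1)
  expect_lt(pred$sd_nm, 0.7)
})

test_that("glycine sites get a synthesised CB and bad sites fail loudly", {
  st <- helix_dimer_fixture(16, separation = 4)
  a <- st$atoms
  gly <- a[!(a$chain == "A" & a$resno == 8 & a$elety == "CB"), ]
  gly$resid[gly$chain == "A" & gly$resno == 8] <- "GLY"
  stg <- structure(list(atoms = gly, source = "gly"), class = "mol_structure")
  ens <- attach_rotamers(stg, list(chain = "A", resno = 8), mode = "quick",
                         seed = 1)
  expect_gt(ens$accepted, 0)
  expect_error(attach_rotamers(st, list(chain = "A", resno = 99)),
               "backbone")
})

test_that("disulfide-bonded cysteines are rejected as label sites", {
  st <- helix_dimer_fixture(16, separation = 4)
  a <- st$atoms
  # fabricate a disulfide: two CYS with SG atoms 2.05 A apart
  ca8 <- unlist(a[a$chain == "A" & a$resno == 8 & a$elety == "CB",
                  c("x", "y", "z")])
  a$resid[a$resno %in% c(8, 9) & a$chain == "A"] <- "CYS"
  sg1 <- data.frame(eleno = 9001, elety = "SG", resid = "CYS", chain = "A",
                    resno = 8, x = ca8[1] + 1.8, y = ca8[2], z = ca8[3],
                    element = "S")
  sg2 <- sg1; sg2$eleno <- 9002; sg2$resno <- 9; sg2$x <- sg1$x + 2.0
  stc <- structure(list(atoms = rbind(a, sg1, sg2), source = "ss"),
                   class = "mol_structure")
  expect_error(attach_rotamers(stc, list(chain = "A", resno = 8)),
               "disulfide")
})
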