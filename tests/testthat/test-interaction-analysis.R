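# Hydrogen-bond detection, occupancy bookkeeping, distance statistics.

# Minimal topology: one donor residue (N-H + backbone) and one ligand
# acceptor, plus optional extras.
donor_acceptor_top <- function() {
  hb <- gen_hbond_series(hbond_series_spec(1, 1, seed = 1))
  hb
}

test_that("donor/acceptor assignment follows the N/O-with-hydrogen rule", {
  hb <- donor_acceptor_top()
  sets <- assign_donors_acceptors(hb$topology, hb$trajectory[1, ])
  # backbone amide N-H is the single donor entry
  expect_equal(nrow(sets$donors), 1)
  expect_equal(hb$topology$elety[sets$donors$d_idx], "N")
  expect_equal(hb$topology$elety[sets$donors$h_idx], "H")
  # every N/O is an acceptor (N, carbonyl O, ligand OXT)
  expect_setequal(hb$topology$elety[sets$acceptors$a_idx],
                  c("N", "O", "OXT"))

  # a lysine-like NZ with three hydrogens gives three donor entries;
  # a C-H hydrogen is not a donor
  top <- topology(data.frame(
    elety = c("NZ", "HZ1", "HZ2", "HZ3", "CB", "HB", "O"),
    resid = c(rep("LYS", 6), "HOH"),
    chain = c(rep("A", 6), "W"),
    resno = c(rep(1, 6), 1),
    elem = c("N", "H", "H", "H", "C", "H", "O"),
    stringsAsFactors = FALSE))
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(3, 0, 0), c(3.9, 0, 0), c(8, 0, 0))
  sets2 <- assign_donors_acceptors(top, coords)
  expect_equal(sum(sets2$donors$d_idx == 1), 3)
  expect_false(5 %in% sets2$donors$d_idx)

  # structures without hydrogens are refused with advice
  top_noh <- topology(data.frame(elety = c("N", "CA", "O"), resid = "GLY",
                                 chain = "A", resno = 1,
                                 elem = c("N", "C", "O"),
                                 stringsAsFactors = FALSE))
  expect_error(assign_donors_acceptors(top_noh, diag(3)),
               "explicit hydrogens")
})

test_that("hbonds_in_frame applies inclusive 3.0 A / 135 degree cutoffs", {
  crit <- hbond_criteria()
  cases <- list(
    list(dist = 2.9, angle = 180, bonded = TRUE),
    list(dist = 3.05, angle = 180, bonded = FALSE),
    list(dist = 2.8, angle = 130, bonded = FALSE),
    list(dist = 3.0, angle = 135, bonded = TRUE)   # both boundaries inclusive
  )
  for (cs in cases) {
    hb <- tryCatch(
      gen_hbond_series(hbond_series_spec(1, 1, seed = 1,
                                         bonded = c(dist = cs$dist,
                                                    angle = cs$angle))),
      error = function(e) NULL)
    if (cs$bonded) {
      expect_false(is.null(hb))
      sets <- assign_donors_acceptors(hb$topology, hb$trajectory[1, ])
      bonds <- hbonds_in_frame(hb$trajectory[1, ], sets, crit)
      expect_equal(nrow(bonds), 1)
    } else {
      # generator itself rejects a 'bonded' geometry failing criteria
      expect_null(hb)
    }
  }
})

test_that("hbonds_in_frame matches a brute-force all-pairs scan", {
  set.seed(17)
  n <- 24
  top <- topology(data.frame(
    elety = paste0(c("N", "H", "O", "C"), rep(1:6, each = 4)),
    resid = "UNK", chain = "A", resno = rep(1:6, each = 4),
    elem = rep(c("N", "H", "O", "C"), 6),
    type = "HETATM", stringsAsFactors = FALSE))
  coords <- matrix(runif(3 * n, 0, 6), ncol = 3)
  # glue each H next to its N so bond inference picks it up
  for (r in 1:6) coords[4 * r - 2, ] <- coords[4 * r - 3, ] + c(1, 0, 0)
  sets <- assign_donors_acceptors(top, coords)
  crit <- hbond_criteria()
  got <- hbonds_in_frame(coords, sets, crit)

  brute <- 0
  for (d in seq_len(n)) {
    for (h in seq_len(n)) {
      for (a in seq_len(n)) {
        if (top$elem[d] %in% c("N", "O") && top$elem[h] == "H" &&
            top$elem[a] %in% c("N", "O") && a != d &&
            top$resno[a] != top$resno[d] &&
            sqrt(sum((coords[d, ] - coords[h, ])^2)) <= 1.2) {
          # h must be bonded to d specifically (nearest heavy atom)
          d2 <- colSums((t(coords[top$elem != "H", , drop = FALSE]) -
                           coords[h, ])^2)
          nearest <- which(top$elem != "H")[which.min(d2)]
          if (nearest != d) next
          dd <- sqrt(sum((coords[d, ] - coords[a, ])^2))
          v1 <- coords[d, ] - coords[h, ]
          v2 <- coords[a, ] - coords[h, ]
          ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
          if (dd <= crit$max_distance && ang >= crit$min_angle) {
            brute <- brute + 1
          }
        }
      }
    }
  }
  expect_equal(nrow(got), brute)
})

test_that("occupancy recovery is exact for constructed series", {
  grouping <- list(protein = data.frame(chain = "A", resno = 1,
                                        subpocket = "S3"),
                   ligand = data.frame(chain = "L", resno = 1,
                                       position = "P3"))
  for (occ in c(0, 0.25, 0.5, 1)) {
    hb <- gen_hbond_series(hbond_series_spec(occ, 1000, seed = 3))
    sets <- assign_donors_acceptors(hb$topology, hb$trajectory[1, ])
    rep <- hbond_occupancy(hb$trajectory, sets, hbond_criteria(), grouping)
    expect_equal(rep$value, occ)
    expect_equal(attr(rep, "total"), occ)
  }
})

test_that("group values sum pair occupancies and totals conserve", {
  # two independent donor-acceptor pairs, both always bonded, one group
  top <- topology(data.frame(
    elety = c("N", "H", "CB", "N", "H", "CB", "O1", "O2"),
    resid = c(rep("GLY", 6), "LIG", "LIG"),
    chain = c("A", "A", "A", "A", "A", "A", "L", "L"),
    resno = c(1, 1, 1, 2, 2, 2, 1, 1),
    elem = c("N", "H", "C", "N", "H", "C", "O", "O"),
    type = c(rep("ATOM", 6), "HETATM", "HETATM"),
    stringsAsFactors = FALSE))
  # donor 1 -> O1 at 2.9 A linear; donor 2 -> O2 likewise; far apart
  coords <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(-1, 1, 0),
    c(0, 50, 0), c(1, 50, 0), c(-1, 51, 0),
    c(2.9, 0, 0), c(2.9, 50, 0))
  traj <- trajectory(rbind(as.numeric(t(coords)), as.numeric(t(coords))))
  sets <- assign_donors_acceptors(top, coords)
  grouping <- list(protein = data.frame(chain = "A", resno = c(1, 2),
                                        subpocket = c("S1", "S1")),
                   ligand = data.frame(chain = "L", resno = 1,
                                       position = "P1"))
  rep <- hbond_occupancy(traj, sets, hbond_criteria(), grouping)
  expect_equal(rep$value, 2)        # sum of two pair occupancies of 1.0
  expect_equal(attr(rep, "total"), 2)
  pairs <- attr(rep, "pairs")
  expect_true(all(pairs$occupancy >= 0 & pairs$occupancy <= 1))
})

test_that("occupancies are frame-order invariant and criteria-monotone", {
  hb <- gen_hbond_series(hbond_series_spec(0.4, 200, seed = 9))
  sets <- assign_donors_acceptors(hb$topology, hb$trajectory[1, ])
  grouping <- list(protein = data.frame(chain = "A", resno = 1,
                                        subpocket = "S2"),
                   ligand = data.frame(chain = "L", resno = 1,
                                       position = "P2"))
  base <- hbond_occupancy(hb$trajectory, sets, hbond_criteria(), grouping)
  perm <- hb$trajectory[sample(200), , drop = FALSE]
  shuf <- hbond_occupancy(trajectory(perm), sets, hbond_criteria(), grouping)
  expect_equal(shuf$value, base$value)
  # loosening cutoffs never decreases occupancy
  loose <- hbond_occupancy(hb$trajectory, sets,
                           hbond_criteria(max_distance = 5, min_angle = 90),
                           grouping)
  expect_gte(loose$value, base$value)
})

test_that("hbond_report sums published per-subpocket occupancies to totals", {
  cols <- list(
    CASP3_com = c(1.37, 2.46, 0.00, 3.04),
    CASP7_com = c(1.99, 2.99, 0.00, 3.30),
    `CASP3-Pro_com` = c(1.38, 3.34, 0.00, 3.13),
    `CASP7-Ser_com` = c(2.03, 3.03, 0.00, 3.17))
  expected_totals <- c(6.87, 8.28, 7.85, 8.23)
  for (i in seq_along(cols)) {
    rep <- hbond_report(data.frame(
      subpocket = c("S4", "S3", "S2", "S1"),
      position = c("P4", "P3", "P2", "P1"),
      value = cols[[i]]))
    expect_equal(attr(rep, "total"), expected_totals[i], tolerance = 1e-12)
  }
})

test_that("distance statistics pool protomers and report population CV", {
  # constant series
  st <- distance_stats(rep(5.31, 100))
  expect_equal(st$mean, 5.31)
  expect_equal(st$sd_percent, 0)
  # two protomers with constant distances 5 and 6
  tr <- gen_trajectory(fluctuation_spec(sigma = c(0, 0), frames = 4, seed = 1))
  top <- tr$topology
  xyz <- matrix(tr$trajectory[1, ], ncol = 3, byrow = TRUE)
  iA <- which(top$chain == "A" & top$resno == 1 & top$elety == "CA")
  jA <- which(top$chain == "A" & top$resno == 2 & top$elety == "CA")
  iB <- which(top$chain == "B" & top$resno == 1 & top$elety == "CA")
  jB <- which(top$chain == "B" & top$resno == 2 & top$elety == "CA")
  xyz[jA, ] <- xyz[iA, ] + c(5, 0, 0)
  xyz[jB, ] <- xyz[iB, ] + c(6, 0, 0)
  tr2 <- trajectory(matrix(rep(as.numeric(t(xyz)), each = 4), nrow = 4))
  pairs <- list(
    list(list(chain = "A", resno = 1, elety = "CA"),
         list(chain = "A", resno = 2, elety = "CA")),
    list(list(chain = "B", resno = 1, elety = "CA"),
         list(chain = "B", resno = 2, elety = "CA")))
  st2 <- distance_stats(tr2, top, pairs)
  expect_equal(st2$mean, 5.5)
  expect_equal(st2$sd_percent, 100 * 0.5 / 5.5, tolerance = 1e-12)
  # missing atoms are named
  bad <- list(list(chain = "A", resno = 99, elety = "CA"),
              list(chain = "A", resno = 1, elety = "CA"))
  expect_error(distance_stats(tr2, top, list(bad)), "A:99:CA not found")
  # CV recovery from the generator
  x <- gen_distance_series(5.62, 19.84, 50000, seed = 12)
  stg <- distance_stats(x)
  expect_equal(stg$mean, 5.62, tolerance = 0.01)
  expect_lt(abs(stg$sd_percent - 19.84), 0.5)
})
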