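# A hand-buildable CA-only chain along the x axis, residues 3.8 A apart.
line_chain <- function(resi, origin = c(0, 0, 0), plddt = 90) {
  n <- length(resi)
  data.frame(resi = resi, atom = "CA",
             x = origin[1] + 3.8 * (seq_len(n) - 1),
             y = origin[2], z = origin[3], plddt = plddt)
}

test_that("quality gates are strict at the published thresholds", {
  tri <- make_toy_trimer(TRUE, 32, seed = 1)
  d <- tri$dimer_1
  expect_true(quality_filter(d)$pass)
  d_edge <- d; d_edge$pdockq <- 0.23
  expect_false(quality_filter(d_edge)$pass)
  expect_identical(quality_filter(d_edge)$reasons, "pdockq")
  d70 <- d
  d70$chain_a$plddt <- 70; d70$chain_b$plddt <- 70
  q <- quality_filter(d70)
  expect_false(q$pass)
  expect_true("if_plddt" %in% q$reasons)
  expect_equal(q$if_plddt, 70)
  # provider clash count: gate applies only when present
  d_clash <- d; d_clash$clash_count <- 6L
  expect_false(quality_filter(d_clash)$pass)
  d_ok <- d; d_ok$clash_count <- 5L
  expect_true(quality_filter(d_ok)$pass)
})

test_that("interface residues match a brute-force all-vs-all distance scan", {
  far <- new_dimer_model("far", "A", "B", line_chain(1:10),
                         line_chain(1:10, origin = c(0, 100, 0)), pdockq = 0.5)
  iface <- interface_residues(far)
  expect_length(iface$chain_a, 0L)
  expect_length(iface$chain_b, 0L)
  near <- new_dimer_model("near", "A", "B", line_chain(1:10),
                          line_chain(1:3, origin = c(0, 3.9, 0)), pdockq = 0.5)
  iface2 <- interface_residues(near)
  expect_gt(length(iface2$chain_a), 0L)
  expect_gt(length(iface2$chain_b), 0L)
  # brute-force oracle on the toy helix fixture
  tri <- make_toy_trimer(TRUE, 30, seed = 3)
  d1 <- tri$dimer_1
  got <- interface_residues(d1, cutoff = 4.0)
  coords <- function(ch) as.matrix(ch[, c("x", "y", "z")])
  ca <- coords(d1$chain_a); cb <- coords(d1$chain_b)
  expected_a <- sort(unique(d1$chain_a$resi[vapply(seq_len(nrow(ca)), function(i)
    min(sqrt(colSums((t(cb) - ca[i, ])^2))) <= 4.0, TRUE)]))
  expected_b <- sort(unique(d1$chain_b$resi[vapply(seq_len(nrow(cb)), function(i)
    min(sqrt(colSums((t(ca) - cb[i, ])^2))) <= 4.0, TRUE)]))
  expect_identical(got$chain_a, expected_a)
  expect_identical(got$chain_b, expected_b)
})

test_that("superposition is exact for self, rigid transforms, and label swaps", {
  tri <- make_toy_trimer(FALSE, 32, seed = 7)
  # self-superposition: duplicate the dimer under a second unique name
  d_dup <- tri$dimer_1
  d_dup$proteins[["b"]] <- "U9"
  self_tri <- as_trimer_candidate(tri$dimer_1, d_dup, common_protein = "C")
  expect_lt(superpose_on_common(self_tri)$rmsd, 1e-9)
  # the generator's random rigid transform is recovered
  expect_lt(superpose_on_common(tri)$rmsd, 1e-6)
  # reference labeling does not change the RMSD
  swapped <- as_trimer_candidate(tri$dimer_2, tri$dimer_1, common_protein = "C")
  expect_lt(abs(superpose_on_common(tri)$rmsd - superpose_on_common(swapped)$rmsd),
            1e-9)
})

test_that("superposition RMSD equals the closed form on a displaced-residue toy", {
  base <- line_chain(1:5)
  moved <- base
  moved$y[3] <- moved$y[3] + 2   # one residue displaced by 2 A, then recenter
  d1 <- new_dimer_model("m1", "C", "U1", base,
                        line_chain(1:3, origin = c(0, 3.9, 0)), pdockq = 0.5)
  d2 <- new_dimer_model("m2", "C", "U2", moved,
                        line_chain(1:3, origin = c(0, 3.9, 0)), pdockq = 0.5)
  tri <- as_trimer_candidate(d1, d2, common_protein = "C")
  got <- superpose_on_common(tri)$rmsd
  # closed form: optimal superposition of 5 matched points computed directly
  # via the Kabsch algebra on centered coordinates
  A <- as.matrix(base[, c("x", "y", "z")])
  B <- as.matrix(moved[, c("x", "y", "z")])
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  sv <- svd(crossprod(Bc, Ac))
  R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  expected <- sqrt(mean(rowSums((Bc %*% t(R) - Ac)^2)))
  expect_equal(got, expected, tolerance = 1e-9)
  expect_gt(got, 0)
  short <- new_dimer_model("m3", "C", "U3", line_chain(101:103),
                           line_chain(1:3, origin = c(0, 3.9, 0)), pdockq = 0.5)
  expect_error(superpose_on_common(
    as_trimer_candidate(d1, short, common_protein = "C")), "fewer than 3")
})

test_that("interface overlap counting follows construction exactly", {
  tri_ov <- superpose_on_common(make_toy_trimer(TRUE, 30, seed = 9))$trimer
  expect_gt(count_interface_overlap(tri_ov)$n_overlap, 10)
  tri_dj <- superpose_on_common(make_toy_trimer(FALSE, 30, seed = 9))$trimer
  expect_identical(count_interface_overlap(tri_dj)$n_overlap, 0L)
  # hand-built 12-residue shared patch: both unique chains touch residues 1..12
  common <- line_chain(1:14)
  u1 <- line_chain(1:12, origin = c(0, 3.9, 0))
  u2 <- line_chain(1:12, origin = c(0, -3.9, 0))
  tri <- as_trimer_candidate(
    new_dimer_model("h1", "C", "U1", common, u1, pdockq = 0.5),
    new_dimer_model("h2", "C", "U2", common, u2, pdockq = 0.5),
    common_protein = "C")
  expect_identical(count_interface_overlap(tri)$n_overlap, 12L)
})

test_that("chain-clash pLDDT sums gate at 500 exactly as arithmetic dictates", {
  # unique chains clash in k coincident residues at pLDDT 90
  clash_case <- function(k) {
    common <- line_chain(1:20)
    u1 <- line_chain(1:10, origin = c(0, 5, 0))
    u2 <- u1
    u2$y[seq_len(nrow(u2)) > k] <- 50   # only the first k residues clash
    tri <- as_trimer_candidate(
      new_dimer_model("c1", "C", "U1", common, u1, pdockq = 0.5),
      new_dimer_model("c2", "C", "U2", common, u2, pdockq = 0.5),
      common_protein = "C")
    chain_clash_screen(tri)
  }
  five <- clash_case(5)
  expect_equal(five$clash_plddt_sum, 450)
  expect_true(five$pass)
  six <- clash_case(6)
  expect_equal(six$clash_plddt_sum, 540)
  expect_false(six$pass)
  none <- clash_case(0)
  expect_equal(none$clash_plddt_sum, 0)
  expect_true(none$pass)
})

test_that("classification returns the constructed verdicts and filter reasons", {
  expect_identical(classify_trimer(make_toy_trimer(TRUE, 32, seed = 11))$verdict,
                   "mutually_exclusive")
  expect_identical(classify_trimer(make_toy_trimer(FALSE, 32, seed = 11))$verdict,
                   "structurally_consistent")
  tri <- make_toy_trimer(TRUE, 32, seed = 12)
  tri$dimer_1$pdockq <- 0.1
  call <- classify_trimer(tri)
  expect_identical(call$verdict, "filtered")
  expect_match(call$filter_reasons, "pdockq")
})

test_that("verdicts are invariant to dimer order and global rigid transforms", {
  rigid <- function(d, seed) {
    rot <- with(list(m = matrix(rnorm(9), 3)), {
      q <- qr.Q(qr(m)); if (det(q) < 0) q[, 1] <- -q[, 1]; q
    })
    shift <- runif(3, -30, 30)
    for (ch in c("chain_a", "chain_b")) {
      xyz <- as.matrix(d[[ch]][, c("x", "y", "z")]) %*% t(rot)
      d[[ch]]$x <- xyz[, 1] + shift[1]
      d[[ch]]$y <- xyz[, 2] + shift[2]
      d[[ch]]$z <- xyz[, 3] + shift[3]
    }
    d
  }
  set.seed(99)
  for (i in 1:10) {
    ov <- i %% 2 == 0
    tri <- make_toy_trimer(ov, 32, seed = i)
    ref <- classify_trimer(tri)$verdict
    moved <- tri
    moved$dimer_1 <- rigid(moved$dimer_1, i)
    moved$dimer_2 <- rigid(moved$dimer_2, i + 100)
    expect_identical(classify_trimer(moved)$verdict, ref)
    flipped <- as_trimer_candidate(tri$dimer_2, tri$dimer_1,
                                   common_protein = tri$common_protein)
    expect_identical(classify_trimer(flipped)$verdict, ref)
  }
})

test_that("pair-call resolution drops homomultimer commons and conflicting verdicts", {
  mk_call <- function(u1, u2, common, verdict) {
    data.frame(unique_1 = u1, unique_2 = u2, common_protein = common,
               verdict = verdict, rmsd_align = 0.5, n_overlap_interface = 12L,
               clash_plddt_sum = NA_real_, filter_reasons = "",
               stringsAsFactors = FALSE)
  }
  calls <- rbind(
    mk_call("X", "Y", "P1", "mutually_exclusive"),
    mk_call("X", "Y", "P3", "mutually_exclusive"),
    mk_call("U", "V", "P1", "mutually_exclusive"),
    mk_call("U", "V", "P2", "structurally_consistent"),
    mk_call("M", "N", "H1", "mutually_exclusive"))
  out <- resolve_pair_calls(calls, homomultimer_ids = "H1")
  expect_identical(nrow(out), 1L)
  expect_identical(out$id_a, "X")
  expect_identical(out$verdict, "mutually_exclusive")
  expect_identical(out$n_support, 2L)
  expect_identical(out$common_proteins, "P1,P3")
})

test_that("dimer models round-trip through minimal PDB files", {
  tri <- make_toy_trimer(TRUE, 24, seed = 21)
  d <- withr::local_tempdir()
  path <- file.path(d, "dimer.pdb")
  write_pdb_dimer(tri$dimer_1, path)
  back <- read_pdb_dimer(path, proteins = c("C", "U1"), pdockq = 0.5)
  expect_equal(back$chain_a$x, tri$dimer_1$chain_a$x, tolerance = 1e-3)
  expect_equal(back$chain_b$z, tri$dimer_1$chain_b$z, tolerance = 1e-3)
  expect_identical(back$chain_a$plddt, rep(90, nrow(back$chain_a)))
  expect_identical(back$chain_a$resi, tri$dimer_1$chain_a$resi)
})
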