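two_atom_pose <- function(gap, source = "AF_MULTIMER", score = 0.9) {
  atoms <- data.frame(chain = c("A", "B"), resno = c(1L, 1L), resid = "ALA",
                      elety = "CA", x = c(0, gap), y = 0, z = 0)
  pose_model("p", source, atoms, "A", "B", raw_score = score)
}

test_that("interface membership uses the 5-Angstrom all-atom rule", {
  near <- interface_residues(two_atom_pose(4.9))
  expect_equal(nrow(near), 2L)          # both residues are interface members
  far <- interface_residues(two_atom_pose(5.1))
  expect_equal(nrow(far), 0L)

  # symmetric in chains: sets agree when computed either way round
  mp <- make_poses(target_size = 30, epitope = 10:25, n_poses = 1,
                   jitter = 0, seed = 1)
  p <- mp$poses[[1]]
  swapped <- pose_model("s", p$source, p$atoms, target_chain = "B",
                        binder_chain = "A", raw_score = p$raw_score)
  i1 <- interface_residues(p)
  i2 <- interface_residues(swapped)
  expect_equal(i1[order(i1$chain, i1$resno), ],
               i2[order(i2$chain, i2$resno), ], ignore_attr = TRUE)

  bad <- p
  bad$atoms$x[3] <- NA
  expect_error(interface_residues(bad), "residue")
})

test_that("interface sets equal the brute-force oracle on random fixtures", {
  set.seed(33)
  for (i in 1:50) {
    n_t <- sample(8:15, 1); n_b <- sample(3:8, 1)
    atoms <- rbind(
      data.frame(chain = "A", resno = rep(seq_len(n_t), each = 2), resid = "ALA",
                 elety = rep(c("CA", "CB"), n_t),
                 x = rnorm(2 * n_t, 0, 6), y = rnorm(2 * n_t, 0, 6),
                 z = rnorm(2 * n_t, 0, 6)),
      data.frame(chain = "B", resno = rep(seq_len(n_b), each = 2), resid = "ALA",
                 elety = rep(c("CA", "CB"), n_b),
                 x = rnorm(2 * n_b, 2, 6), y = rnorm(2 * n_b, 2, 6),
                 z = rnorm(2 * n_b, 2, 6)))
    pose <- pose_model("r", "NMR_HADDOCK", atoms, "A", "B")
    got <- interface_residues(pose)
    ora <- interface_oracle(atoms, "A", "B")
    expect_equal(got$resno[got$chain == "A"], ora$target)
    expect_equal(got$resno[got$chain == "B"], ora$binder)
  }
})

test_that("interface agrees with the bio3d binding.site reference", {
  mp <- make_poses(target_size = 40, epitope = 12:27, n_poses = 1,
                   jitter = 0.3, seed = 8)
  dir <- file.path(tempdir(), "poses_ref")
  sc <- write_poses(mp$poses, dir)
  pdb <- bio3d::read.pdb(sc$file[1], verbose = FALSE)
  bs <- bio3d::binding.site(pdb,
                            a.inds = bio3d::atom.select(pdb, chain = "A", verbose = FALSE),
                            b.inds = bio3d::atom.select(pdb, chain = "B", verbose = FALSE),
                            cutoff = 5, verbose = FALSE)
  mine <- interface_residues(mp$poses[[1]])
  expect_setequal(bs$resno, mine$resno[mine$chain == "A"])
})

test_that("pose weights follow the source conventions", {
  expect_equal(pose_weight(two_atom_pose(4, "AF_MULTIMER", 0.83)), 0.83)
  expect_equal(pose_weight(two_atom_pose(4, "ADCP", -12.5)), 12.5)
  expect_equal(pose_weight(two_atom_pose(4, "ADCP", 3)), 0)  # floored
  nmr <- two_atom_pose(4, "NMR_HADDOCK", NULL)
  expect_equal(pose_weight(nmr), 1)
  af_none <- two_atom_pose(4, "AF_MULTIMER", NULL)
  expect_error(pose_weight(af_none), "raw score")
  # ADCP ranking preserved: lower free energy, larger weight
  expect_gt(pose_weight(two_atom_pose(4, "ADCP", -15)),
            pose_weight(two_atom_pose(4, "ADCP", -10)))
})

test_that("weighted proximity normalises the maximum residue to 100", {
  mp <- make_poses(target_size = 40, epitope = 15:30, n_poses = 1,
                   jitter = 0, seed = 2)
  wp1 <- weighted_proximity(mp$poses)
  iface <- interface_residues(mp$poses[[1]])
  in_if <- as.character(iface$resno[iface$chain == "A"])
  expect_true(all(wp1[in_if] == 100))        # single pose: all-or-nothing
  expect_true(all(wp1[setdiff(names(wp1), in_if)] == 0))

  # two equal-weight poses, residue in both vs residue in one: 100 vs 50
  shift_pose <- function(p, dx, id) {
    at <- p$atoms
    at$x[at$chain == "B"] <- at$x[at$chain == "B"] + dx
    pose_model(id, p$source, at, "A", "B", p$raw_score)
  }
  base <- mp$poses[[1]]
  shifted <- shift_pose(base, 10 * 3.8, "p2")   # binder moved 10 residues right
  wp2 <- weighted_proximity(list(base, shifted))
  i_base <- interface_residues(base)$resno[interface_residues(base)$chain == "A"]
  i_shift <- interface_residues(shifted)$resno[interface_residues(shifted)$chain == "A"]
  both <- intersect(i_base, i_shift)
  only <- setdiff(i_base, i_shift)
  expect_true(all(wp2[as.character(both)] == 100))
  expect_true(all(wp2[as.character(only)] == 50))
  expect_equal(max(wp2), 100)

  # invariant to uniform weight rescaling
  rescored <- lapply(list(base, shifted), function(p)
    pose_model(p$pose_id, p$source, p$atoms, "A", "B", p$raw_score * 7))
  expect_equal(weighted_proximity(rescored), wp2)

  # profile support is inside the union of per-pose interface sets
  expect_true(all(as.integer(names(wp2)[wp2 > 0]) %in% union(i_base, i_shift)))

  # empty interface: all-zero profile with a warning
  apart <- base
  apart$atoms$y[apart$atoms$chain == "B"] <- 1e4
  apart <- pose_model("far", base$source, apart$atoms, "A", "B", base$raw_score)
  expect_warning(wp0 <- weighted_proximity(list(apart)), "no interface")
  expect_true(all(wp0 == 0))

  # inconsistent target numbering across poses errors
  renum <- base
  renum$atoms$resno[renum$atoms$chain == "A"] <-
    renum$atoms$resno[renum$atoms$chain == "A"] + 100L
  renum <- pose_model("renum", base$source, renum$atoms, "A", "B", base$raw_score)
  expect_error(weighted_proximity(list(base, renum)), "numbering")
})

test_that("contact profile averages cross-chain atom pairs per pose", {
  atoms <- data.frame(chain = c("A", "A", "B"), resno = c(1L, 2L, 1L),
                      resid = "ALA", elety = "CA",
                      x = c(0, 4, 0), y = c(0, 0, 4), z = 0)
  pose <- pose_model("c", "NMR_HADDOCK", atoms, "A", "B")
  cp <- contact_profile(list(pose))
  # binder atom within 5 A of one A atom (4.0) but not the other (5.66)
  expect_equal(unname(cp["1"]), 1)

  far <- atoms; far$y[3] <- 100
  pose_far <- pose_model("f", "NMR_HADDOCK", far, "A", "B")
  expect_true(all(contact_profile(list(pose_far)) == 0))

  # averaging over two poses
  cp2 <- contact_profile(list(pose, pose_far))
  expect_equal(unname(cp2["1"]), 0.5)

  # brute-force oracle on random fixtures: total contacts per residue
  set.seed(44)
  for (i in 1:50) {
    n_t <- sample(5:10, 1); n_b <- sample(2:6, 1)
    atoms <- rbind(
      data.frame(chain = "A", resno = seq_len(n_t), resid = "ALA", elety = "CA",
                 x = rnorm(n_t, 0, 4), y = rnorm(n_t, 0, 4), z = rnorm(n_t, 0, 4)),
      data.frame(chain = "B", resno = seq_len(n_b), resid = "ALA", elety = "CA",
                 x = rnorm(n_b, 0, 4), y = rnorm(n_b, 0, 4), z = rnorm(n_b, 0, 4)))
    pose <- pose_model("r", "NMR_HADDOCK", atoms, "A", "B")
    got <- contact_profile(list(pose))
    for (rb in seq_len(n_b)) {
      cnt <- 0
      for (it in which(atoms$chain == "A")) {
        ib <- which(atoms$chain == "B" & atoms$resno == rb)
        d <- sqrt((atoms$x[it] - atoms$x[ib])^2 + (atoms$y[it] - atoms$y[ib])^2 +
                  (atoms$z[it] - atoms$z[ib])^2)
        cnt <- cnt + sum(d <= 5)
      }
      expect_equal(unname(got[as.character(rb)]), cnt)
    }
  }
})

test_that("profiles map onto gapped alignments and round-trip", {
  scores <- setNames(c(10, 20, 30, 40), 1:4)
  expect_equal(map_profile_to_alignment(scores, "ACDE", "ACDE"),
               c(10, 20, 30, 40))
  gapped <- map_profile_to_alignment(scores, "AC-DE", "ACDE")
  expect_equal(gapped, c(10, 20, NA, 30, 40))
  # removing gaps recovers the original profile
  expect_equal(gapped[!is.na(gapped)], unname(scores))
  expect_error(map_profile_to_alignment(scores, "AC-DF", "ACDE"), "mismatch")
})

test_that("pose ensembles round-trip through PDB files and score sidecars", {
  mp <- make_poses(target_size = 30, epitope = 5:20, n_poses = 3,
                   jitter = 0.2, seed = 21, source = "ADCP")
  dir <- file.path(tempdir(), "poses_rt")
  sc <- write_poses(mp$poses, dir)
  expect_true(file.exists(file.path(dir, "scores.tsv")))
  back <- read_poses(sc$file, sc, "A", "B")
  expect_equal(weighted_proximity(back), weighted_proximity(mp$poses))
  expect_equal(contact_profile(back), contact_profile(mp$poses))
})
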