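test_that("renumbering is continuous, cumulative and bijective", {
  # two-chain toy
  m <- renumber_chains(data.frame(chain_id = c("L", "H"), n_res = c(3, 3)))
  expect_equal(m$residue_index, 1:6)

  # antibody-sized four-chain layout: cumulative offsets
  m4 <- renumber_chains(data.frame(chain_id = c("L", "H", "l", "h"),
                                   n_res = c(214, 445, 214, 445)))
  expect_equal(max(m4$residue_index), 1318)
  expect_equal(m4$residue_index[m4$chain_id == "L"], 1:214)
  expect_equal(m4$residue_index[m4$chain_id == "h"][1], 874)

  # identity on a single chain
  m1 <- renumber_chains(data.frame(chain_id = "A", n_res = 5))
  expect_equal(m1$resno, m1$residue_index)

  # bijection: inverse lookup recovers (chain, author number)
  back <- lookup_residue(m4, sample(1:1318))
  expect_equal(back$residue_index,
               m4$residue_index[match(paste(back$chain_id, back$resno),
                                      paste(m4$chain_id, m4$resno))])
  expect_equal(anyDuplicated(m4$residue_index), 0L)

  expect_error(renumber_chains(data.frame(chain_id = "A", n_res = 0)),
               class = "allopath_validation_error")
})

test_that("PDB structures parse with roles, ordering and error contracts", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path)
  st <- read_structure(path, chain_roles = c(L = "light", H = "heavy"))
  expect_s3_class(st, "allopath_structure")
  expect_equal(nrow(st$atoms), 7)
  expect_equal(max(st$atoms$residue_index), 6)
  expect_equal(st$chains$chain_id, c("L", "H"))
  expect_equal(st$atoms$residue_index[st$atoms$chain == "H"], 4:6)
  # element inference and masses present
  expect_equal(st$atoms$element[1], "N")
  expect_true(all(st$atoms$mass > 0))

  # ligand chain appended after protein chains in global numbering
  lig <- c(readLines(path)[1:7],
           sprintf("HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   8L, "C1", "LIG", "X", 1L, 20, 20, 20, "C"),
           "END")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lig, path2)
  st2 <- read_structure(path2, chain_roles = c(X = "ligand"))
  expect_equal(st2$atoms$residue_index[st2$atoms$chain == "X"], 7)

  # malformed coordinate -> format error naming the line
  bad <- readLines(path)
  bad[3] <- paste0(substr(bad[3], 1, 30), "  xx.xxx", substr(bad[3], 39, nchar(bad[3])))
  path3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, path3)
  expect_error(read_structure(path3), "line 3", class = "allopath_format_error")

  # duplicate (chain, resno, atom name) -> validation error
  dup <- c(readLines(path)[1:7], readLines(path)[7], "END")
  path4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(dup, path4)
  expect_error(read_structure(path4), "duplicate",
               class = "allopath_validation_error")
})

test_that("trajectories read from multi-model PDB and XYZ with frame validation", {
  spath <- withr::local_tempfile(fileext = ".pdb")
  tpath <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(spath)
  write_toy_pdb(tpath, models = 3)
  st <- read_structure(spath)
  traj <- read_trajectory(tpath, st)
  expect_equal(traj$n_frames, 3)
  expect_equal(dim(traj$coords), c(3, 7, 3))
  # frames shift by +1 A in x per model
  expect_equal(traj$coords[2, , 1] - traj$coords[1, , 1], rep(1, 7))

  # single model -> one frame
  expect_equal(read_trajectory(spath, st)$n_frames, 1)

  # frame with missing atom -> error naming the frame
  lines <- readLines(tpath)
  atom_lines <- grep("^ATOM", lines)
  bad <- lines[-atom_lines[10]]  # drop an atom from frame 2
  tpath2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, tpath2)
  expect_error(read_trajectory(tpath2, st), "frame 2",
               class = "allopath_validation_error")

  # XYZ round-trip preserves coordinates
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, xyz)
  traj2 <- read_trajectory(xyz, st)
  expect_equal(traj2$coords, traj$coords, tolerance = 1e-9)
})

test_that("PDB coordinate parsing agrees with bio3d", {
  skip_if_not_installed("bio3d")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path)
  st <- read_structure(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(unname(as.matrix(st$atoms[, c("x", "y", "z")])),
               unname(matrix(ref$xyz, ncol = 3, byrow = TRUE)))
})

test_that("matrix writer round-trips exactly and validates shape", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(diag(3), path)
  expect_equal(unname(read_matrix(path)), diag(3))

  # full-precision round trip on an irrational-valued symmetric matrix
  set.seed(5)
  A <- crossprod(matrix(rnorm(25), 5))
  M <- A / sqrt(outer(diag(A), diag(A)))
  write_matrix(M, path, labels = 11:15)
  back <- read_matrix(path)
  expect_identical(unname(back), unname(M))
  expect_equal(rownames(back), as.character(11:15))

  expect_error(write_matrix(matrix(1, 2, 3), path),
               class = "allopath_validation_error")
  expect_error(write_matrix(diag(3), path, labels = 1:2),
               class = "allopath_validation_error")
})

test_that("structure and renumber map survive a PDB write/read cycle", {
  gen <- generate_ensemble(ensemble_spec(
    8, n_frames = 3, seed = 4,
    chains = data.frame(chain_id = c("L", "H"), role = c("light", "heavy"),
                        n_res = c(4, 4))))
  spath <- withr::local_tempfile(fileext = ".pdb")
  tpath <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(gen$structure, spath)
  write_pdb(gen$trajectory, tpath)
  st <- read_structure(spath, chain_roles = c(L = "light", H = "heavy"))
  expect_equal(st$renumber_map, gen$structure$renumber_map)
  traj <- read_trajectory(tpath, st)
  expect_equal(traj$coords, gen$trajectory$coords, tolerance = 1e-3)  # PDB prints 3 decimals

  jpath <- withr::local_tempfile(fileext = ".json")
  write_renumber_map(st, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(as.data.frame(back), st$renumber_map)
})
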