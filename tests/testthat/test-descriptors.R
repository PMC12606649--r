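# The 66-descriptor region block, the nearest/around blocks, the cofactor
# inventory, and assembly of the 765-feature vector.

test_that("region block of an empty region is all zero and 66 long", {
  v <- region_descriptors(character())
  expect_length(v, 66L)
  expect_true(all(v == 0))
})

test_that("homogeneous regions reproduce hand-summed property values", {
  tab <- aa_properties()
  v <- region_descriptors(c("GLY", "GLY", "GLY"))
  expect_equal(unname(v["n.res"]), 3)
  expect_equal(unname(v["n.polar.neutral"]), 0)
  expect_equal(unname(v["n.hydrophobic"]), 3 * tab["GLY", "hydrophobic"])
  expect_equal(unname(v["n.glypro"]), 3)
  expect_equal(unname(v["n.aa.GLY"]), 3)
  expect_equal(unname(v["sum.hydropathy"]), 3 * tab["GLY", "hydropathy"])
  expect_equal(unname(v["sum.volume"]), 3 * tab["GLY", "volume"])
  expect_equal(unname(v["mean.flexibility"]), tab["GLY", "flexibility"])
  expect_equal(unname(v["sum.steric.flex"]), 3 * tab["GLY", "steric.flex"])
})

test_that("Cys is polar-neutral while His and Lys count as basic", {
  v <- region_descriptors(c("CYS", "HIS", "LYS"))
  expect_equal(unname(v["n.cys"]), 1)
  expect_equal(unname(v["n.his"]), 1)
  expect_equal(unname(v["n.basic"]), 2)  # His + Lys
  expect_equal(unname(v["n.polar.neutral"]), 1)  # Cys only
})

test_that("non-canonical residues follow the configured policy", {
  expect_warning(v <- region_descriptors(c("GLY", "MSE")), "MSE")
  expect_equal(unname(v["n.res"]), 1)
  expect_error(region_descriptors(c("GLY", "MSE"), on_noncanonical = "error"),
               "MSE")
})

test_that("the default schema is 765 features with the documented blocks", {
  sc <- feature_schema("A", r1 = 11, r2 = 4)
  expect_equal(nrow(sc), 765L)
  expect_false(anyDuplicated(sc$name) > 0)
  for (b in c("Protein", "Bar", "Shell1", "CofAtom.Fe", "CofAtom.S",
              "CofAtom.Fe1", "CofAtom.Fe2", "CofAtom.S1", "CofAtom.S2",
              "CofAtom.All"))
    expect_equal(sum(sc$block == b), 66L, info = b)
  expect_equal(sum(startsWith(sc$name, "NearestFe.")) +
                 sum(startsWith(sc$name, "NearestS.")), 28L)
  expect_equal(sum(startsWith(sc$name, "AroundFe.")) +
                 sum(startsWith(sc$name, "AroundS.")), 32L)
  expect_equal(sum(sc$block == "Inventory"), 42L)
  expect_equal(sum(sc$scale == "condition"), 1L)
  expect_error(feature_schema("A", r1 = 4, r2 = 4), "smaller")
  # variant schema appends the one-hot technique block
  expect_equal(nrow(feature_schema("A", 11, 4, technique = TRUE)), 770L)
})

test_that("long-range block counts the whole chain, coordinate-free", {
  toy <- small_fe2s2(seed = 11, residues = rep("ALA", 6),
                     shells = c(4, 6, 8, 10, 12, 14))
  st <- toy$structure
  lr <- long_range(st)
  expect_equal(unname(lr["n.res"]), 10)  # 6 shell + 4 ligands
  expect_equal(unname(lr["n.cys"]), 4)
  # brute-force recount from the atom table
  a <- st$atoms
  codes <- a$resid[!a$het & !duplicated(paste(a$chain, a$resno))]
  expect_equal(unname(lr["n.aa.ALA"]), sum(codes == "ALA"))
  # translation leaves the block unchanged
  a$x <- a$x + 11.3
  expect_equal(long_range(new_fes_structure(a, id = "t")), lr)
})

test_that("medium-range block saturates to the whole protein and nests", {
  toy <- small_fe2s2(seed = 12, residues = c("ALA", "HIS", "SER"),
                     shells = c(4, 9, 12))
  st <- toy$structure
  site <- detect_cluster_sites(st)[[1]]
  expect_warning(sat <- medium_range(st, site, 100), "outside")
  expect_equal(unname(sat), unname(long_range(st)))
  m10 <- suppressWarnings(medium_range(st, site, 10))
  # ligands (~2.3 A) plus the 4 and 9 A shells are inside 10 A
  expect_equal(unname(m10["n.res"]), 6)
  b8 <- medium_range(st, site, 8)
  b16 <- medium_range(st, site, 16)
  counts <- grep("^n\\.", names(b8))
  expect_true(all(b16[counts] >= b8[counts]))
})

test_that("short-range blocks are per element, zero-filled for mono sites", {
  mono <- make_toy_structure(toy_structure_spec("mono_fe", seed = 13))
  site <- detect_cluster_sites(mono$structure)[[1]]
  v <- short_range(mono$structure, site, 4)
  expect_length(v, 132L)
  s_half <- v[startsWith(names(v), "CofAtom.S.")]
  expect_true(all(s_half == 0))
  fe_half <- v[startsWith(names(v), "CofAtom.Fe.")]
  # four Cys ligating atoms at 2.3 A are within any r2 >= 3
  expect_equal(unname(fe_half["CofAtom.Fe.n.cys"]), 4)

  toy <- small_fe2s2(seed = 14)
  site2 <- detect_cluster_sites(toy$structure)[[1]]
  v3 <- short_range(toy$structure, site2, 3)
  v5 <- short_range(toy$structure, site2, 5)
  expect_gte(v3[["CofAtom.Fe.n.cys"]], 1)
  counts <- grepl("\\.n\\.", names(v3)) | grepl("\\.n\\.res$", names(v3))
  expect_true(all(v5[counts] >= v3[counts]))
})

test_that("nearest-residue blocks resolve ties by chain then residue number", {
  mono <- make_toy_structure(toy_structure_spec(
    "mono_fe", ligands = c("HIS", "CYS", "CYS", "CYS"), seed = 15))
  st <- mono$structure
  site <- detect_cluster_sites(st)[[1]]
  v <- nearest_residue_descriptors(st, site)
  expect_length(v, 28L)
  # all four ligating atoms sit at exactly 2.3 A from Fe; the tie breaks to
  # the lowest residue number, which is the His ligand
  his_resno <- min(site$coord_residues$resno)
  expect_equal(site$coord_residues$resid[site$coord_residues$resno == his_resno],
               "HIS")
  expect_equal(unname(v["NearestFe.flag.is.his"]), 1)
  # mononuclear: the S half is zero-filled
  expect_true(all(v[startsWith(names(v), "NearestS.")] == 0))
})

test_that("around blocks aggregate the sequence triplet, termini truncate", {
  tab <- aa_properties()
  mk_res <- function(resno, resid, x) {
    data.frame(eleno = resno * 10 + (0:2), elety = c("CA", "CB", "N"),
               resid = resid, chain = "A", resno = resno, insert = "",
               x = x + c(0, 0.8, 1.6), y = 0, z = 0, occ = 1, altloc = "",
               element = c("C", "C", "N"), het = FALSE,
               stringsAsFactors = FALSE)
  }
  fe <- data.frame(eleno = 999, elety = "FE", resid = "FE", chain = "A",
                   resno = 99, insert = "", x = -3, y = 0, z = 0, occ = 1,
                   altloc = "", element = "FE", het = TRUE,
                   stringsAsFactors = FALSE)
  # nearest residue is SER at resno 1 (chain start): triplet is {1, 2}
  st <- new_fes_structure(rbind(mk_res(1, "SER", 0), mk_res(2, "CYS", 6),
                                mk_res(3, "SER", 12), fe), id = "tri")
  site <- detect_cluster_sites(st)[[1]]
  v <- around_descriptors(st, site)
  expect_length(v, 32L)
  expect_equal(unname(v["AroundFe.sum.flexibility"]),
               tab["SER", "flexibility"] + tab["CYS", "flexibility"])
  # centered nearest residue: full {SER, CYS, SER} triplet, hand-summed
  st2 <- new_fes_structure(rbind(mk_res(1, "SER", -6), mk_res(2, "CYS", 0),
                                 mk_res(3, "SER", 6),
                                 transform(fe, x = 2.5)), id = "tri2")
  site2 <- detect_cluster_sites(st2)[[1]]
  v2 <- around_descriptors(st2, site2)
  expect_equal(unname(v2["AroundFe.sum.flexibility"]),
               2 * tab["SER", "flexibility"] + tab["CYS", "flexibility"])
  expect_equal(unname(v2["AroundFe.sum.bulkiness"]),
               2 * tab["SER", "bulkiness"] + tab["CYS", "bulkiness"])
  expect_equal(unname(v2["AroundFe.sum.steric.flex"]),
               2 * tab["SER", "steric.flex"] + tab["CYS", "steric.flex"])
  expect_equal(unname(v2["AroundFe.n.polar.neutral"]), 3)
})

test_that("cofactor inventory counts others by scope, excluding the site", {
  bare <- small_fe2s2(seed = 16)
  site <- detect_cluster_sites(bare$structure)[[1]]
  inv <- cofactor_inventory(bare$structure, site, r1 = 10, r2 = 4)
  expect_length(inv, 44L)
  expect_true(all(inv[grep("^Global.Inv", names(inv))] == 0))
  expect_equal(unname(inv["Global.Site.n.fe"]), 2)
  expect_equal(unname(inv["Global.Site.n.s"]), 2)

  withfad <- make_toy_structure(toy_structure_spec(
    "fe2s2", residues = c("ALA", "SER"), shells = c(5, 9), seed = 17,
    extra_cofactors = data.frame(code = "FAD", distance = 6)))
  site2 <- detect_cluster_sites(withfad$structure)[[1]]
  inv2 <- cofactor_inventory(withfad$structure, site2, r1 = 10, r2 = 4)
  expect_equal(unname(inv2["Global.Inv.FAD.whole"]), 1)
  expect_equal(unname(inv2["Global.Inv.FAD.r1"]), 1)
  expect_equal(unname(inv2["Global.Inv.FAD.r2"]), 0)

  two <- make_toy_structure(toy_structure_spec(
    "fe2s2", residues = c("ALA", "SER"), shells = c(5, 9), seed = 18,
    extra_cofactors = data.frame(code = c("FES", "FES", "XYZ"),
                                 distance = c(20, 30, 12))))
  site3 <- detect_cluster_sites(two$structure)[[1]]
  inv3 <- cofactor_inventory(two$structure, site3, r1 = 10, r2 = 4)
  expect_equal(unname(inv3["Global.Inv.FES.whole"]), 2)
  # unknown code buckets into OTHER
  expect_equal(unname(inv3["Global.Inv.OTHER.whole"]), 1)
})

test_that("featurize emits a deterministic 765-vector with pH in its slot", {
  toy <- small_fe2s2(seed = 19)
  st <- toy$structure
  site <- detect_cluster_sites(st)[[1]]
  v1 <- featurize(st, site, r1 = 11, r2 = 4, ph = 6.5)
  expect_length(v1, 765L)
  expect_equal(unname(v1["Global.pH"]), 6.5)
  v2 <- featurize(st, site, r1 = 11, r2 = 4, ph = 6.5)
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_error(featurize(st, site, r1 = 4, r2 = 4, ph = 7), "smaller")
  expect_error(featurize(st, site, r1 = 11, r2 = 4, ph = 15), "pH")
  # count features are nonnegative integers; class counts bounded by totals
  sc <- feature_schema("A", 11, 4)
  counts <- v1[sc$name[sc$count_type]]
  expect_true(all(counts >= 0 & counts == round(counts)))
  expect_true(all(v1["Protein.n.polar.neutral"] <= v1["Protein.n.res"]))
})

test_that("mononuclear sites zero-fill every inorganic-S block", {
  mono <- make_toy_structure(toy_structure_spec("mono_fe", seed = 20))
  site <- detect_cluster_sites(mono$structure)[[1]]
  v <- featurize(mono$structure, site, r1 = 11, r2 = 4, ph = 7)
  szero <- startsWith(names(v), "CofAtom.S.") |
    startsWith(names(v), "CofAtom.S1.") | startsWith(names(v), "CofAtom.S2.") |
    startsWith(names(v), "NearestS.") | startsWith(names(v), "AroundS.")
  expect_true(all(v[szero] == 0))
  expect_equal(unname(v["Global.Site.n.s"]), 0)
})

test_that("count features grow monotonically with the radii", {
  sc <- feature_schema("A", 11, 4)
  for (s in c(21, 22)) {
    toy <- make_toy_structure(toy_structure_spec(
      site_kind = if (s %% 2) "fe2s2" else "mono_fe", seed = s))
    st <- toy$structure
    site <- detect_cluster_sites(st)[[1]]
    prev <- NULL
    for (r1 in 8:16) {
      v <- featurize(st, site, r1 = r1, r2 = 3, ph = 7, schema = sc)
      cur <- v[sc$name[sc$count_type & sc$radius == "r1"]]
      if (!is.null(prev)) expect_true(all(cur >= prev))
      prev <- cur
    }
    prev <- NULL
    for (r2 in 3:5) {
      v <- featurize(st, site, r1 = 16, r2 = r2, ph = 7, schema = sc)
      cur <- v[sc$name[sc$count_type & sc$radius == "r2"]]
      if (!is.null(prev)) expect_true(all(cur >= prev))
      prev <- cur
    }
  }
})

test_that("every feature is invariant under rigid motion", {
  toy <- small_fe2s2(seed = 23)
  st <- toy$structure
  site <- detect_cluster_sites(st)[[1]]
  v <- featurize(st, site, r1 = 11, r2 = 4, ph = 7)
  th <- 1.1; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  a <- st$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 5.5; a$y <- xyz[, 2] - 3.1; a$z <- xyz[, 3] + 0.7
  st2 <- new_fes_structure(a, id = "rt")
  site2 <- detect_cluster_sites(st2)[[1]]
  v2 <- featurize(st2, site2, r1 = 11, r2 = 4, ph = 7)
  expect_lt(max(abs(v - v2)), 1e-9)
})

test_that("strategy B is the deduplicated union of all strategy-A vectors", {
  scB <- feature_schema("B")
  toy <- small_fe2s2(seed = 24)
  st <- toy$structure
  site <- detect_cluster_sites(st)[[1]]
  vB <- featurize_all_radii(st, site, ph = 7, schema = scB)
  expect_equal(length(vB), nrow(scB))
  # name-set algebra: A features across all 27 radii pairs map exactly onto B
  mapped <- character()
  npairs <- 0L
  for (r1 in 8:16) for (r2 in 3:5) {
    npairs <- npairs + 1L
    sa <- feature_schema("A", r1 = r1, r2 = r2)
    mapped <- union(mapped, schema_a_names_in_b(sa))
  }
  expect_equal(npairs, 27L)
  expect_setequal(mapped, scB$name)
  # block equality: the B slots at (11, 4) equal the standalone A vector
  sa <- feature_schema("A", 11, 4)
  vA <- featurize(st, site, r1 = 11, r2 = 4, ph = 7, schema = sa)
  expect_equal(as.numeric(vB[schema_a_names_in_b(sa)]), as.numeric(vA))
  # radius-independent blocks appear once and equal the A values
  expect_equal(vB["Protein.n.res"], vA["Protein.n.res"])
  expect_equal(sum(startsWith(scB$name, "Bar.")), 9L * 66L)
  expect_equal(sum(grepl("^CofAtom\\.", scB$name)), 3L * 7L * 66L)
})
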