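# Shared fixtures and independent oracles for the test suite.

# Independent brute-force neighborhood oracle: plain double loop over residues
# and atoms, no shared code with residues_within().
brute_force_within <- function(structure, centers, radius) {
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1)
  a <- structure$atoms
  a <- a[!a$het & a$resid %in% rownames(aa_properties()), , drop = FALSE]
  keys <- unique(paste(a$chain, a$resno, a$insert, sep = ":"))
  hit <- character()
  for (k in keys) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    sel <- a$chain == parts[1] & a$resno == as.integer(parts[2]) &
      a$insert == ifelse(length(parts) > 2, parts[3], "")
    ra <- a[sel, , drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(centers))) {
        d <- sqrt((ra$x[i] - centers[j, 1])^2 + (ra$y[i] - centers[j, 2])^2 +
                    (ra$z[i] - centers[j, 3])^2)
        # same documented predicate: boundary inclusive at 1e-9 A tolerance
        if (d <= radius + 1e-9) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hit <- c(hit, k)
  }
  sort(hit)
}

# Minimal hand-written PDB text (column-exact) for parser edge cases.
pdb_line <- function(type = "ATOM", eleno, elety, alt = " ", resid, chain,
                     resno, x, y, z, occ = 1, elesy) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, elety, alt, resid, chain, resno, x, y, z, occ, 0,
          elesy)
}

# A tiny fe2s2 fixture: known cluster, 4 Cys ligands, controllable shells.
small_fe2s2 <- function(seed = 1, residues = c("ALA", "HIS", "SER"),
                        shells = c(4.5, 9.5, 12.5), ...) {
  make_toy_structure(toy_structure_spec(
    site_kind = "fe2s2", residues = residues, shells = shells,
    seed = seed, ...))
}

# reduced settings that keep CV-based tests fast
tiny_grid <- function() list(max_depth = 3, n_estimators = 60,
                             learning_rate = 0.3, min_child_weight = 2)
small_grid <- function() list(max_depth = c(3, 4), n_estimators = 100,
                              learning_rate = c(0.1, 0.2),
                              min_child_weight = 5)
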