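# Curated-table loading and design-matrix assembly. The experimental table is
# delimited text with one row per measurement; a small alias map absorbs the
# common header dialects so files exported from other tools load unchanged.

.col_aliases <- list(
  entry_id = c("entry_id", "entry", "id"),
  structure = c("structure", "structure_ref", "pdb", "pdb_id", "pdb_file",
                "file", "path"),
  site_chain = c("site_chain", "chain", "cluster_chain"),
  site_resno = c("site_resno", "site_residue", "cluster_resno", "resno"),
  rp_mv = c("rp_mv", "rp", "rp(mv)", "rp_mV", "redox_potential_mv", "e0_mv",
            "em_mv"),
  ph = c("ph"),
  class = c("class", "protein_class", "protein_type", "type", "family"),
  technique = c("technique", "method", "exp_technique"),
  resolution = c("resolution", "resolution_a", "res_a"),
  mutation = c("mutation", "mutation_label", "mutant", "variant"),
  protein_id = c("protein_id", "parent", "parent_protein", "protein")
)

.known_classes <- c("ferredoxin", "mitoneet", "rieske", "rubredoxin", "other")

#' Load a curated experimental data set
#'
#' Reads the delimited experiment table (comma or tab, autodetected), maps
#' header aliases onto the canonical column names, validates every row and
#' reports all problems at once. Required columns: entry id, structure
#' reference, reduction potential (mV), pH and protein class. The reduction
#' potential must lie in \[-1000, 1000\] mV, pH in \[0, 14\], entry ids must
#' be unique and the class must be one of ferredoxin / mitoNEET / rieske /
#' rubredoxin / other (case-insensitive).
#'
#' @param path path to the delimited table.
#' @param verbose print the composition summary (entries per class, RP range).
#' @return data.frame with canonical columns `entry_id`, `structure`,
#'   `site_chain`, `site_resno`, `rp_mv`, `ph`, `class`, `technique`,
#'   `resolution`, `mutation`, `protein_id`, `is_mutant`; the per-class
#'   counts and RP range are attached as attribute `summary`.
#' @export
load_dataset <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stop("data set table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  lc <- tolower(trimws(colnames(raw)))
  out <- list()
  for (canon in names(.col_aliases)) {
    hit <- which(lc %in% tolower(.col_aliases[[canon]]))
    out[[canon]] <- if (length(hit)) raw[[hit[1]]] else NA
  }
  n <- nrow(raw)
  ent <- data.frame(
    entry_id = as.character(out$entry_id),
    structure = as.character(out$structure),
    site_chain = if (all(is.na(out$site_chain))) NA_character_ else
      as.character(out$site_chain),
    site_resno = suppressWarnings(as.integer(out$site_resno)),
    rp_mv = suppressWarnings(as.numeric(out$rp_mv)),
    ph = suppressWarnings(as.numeric(out$ph)),
    class = tolower(trimws(as.character(out$class))),
    technique = if (all(is.na(out$technique))) NA_character_ else
      as.character(out$technique),
    resolution = suppressWarnings(as.numeric(out$resolution)),
    mutation = if (all(is.na(out$mutation))) "WT" else
      ifelse(is.na(out$mutation) | !nzchar(out$mutation), "WT",
             as.character(out$mutation)),
    stringsAsFactors = FALSE
  )
  ent$protein_id <- if (all(is.na(out$protein_id))) {
    base <- sub("\\.[^.]*$", "", basename(ent$structure))
    sub("_(m|mut)[0-9]+$", "", base)
  } else as.character(out$protein_id)
  ent$is_mutant <- ent$mutation != "WT"

  problems <- character()
  need <- c("entry_id", "structure", "rp_mv", "ph", "class")
  for (canon in need)
    if (length(out[[canon]]) == 1 && all(is.na(out[[canon]])))
      problems <- c(problems, paste0("required column missing: ", canon))
  if (!length(problems)) {
    dup <- ent$entry_id[duplicated(ent$entry_id)]
    if (length(dup))
      problems <- c(problems,
                    paste0("duplicate entry_id: ", paste(unique(dup), collapse = ", ")))
    for (i in seq_len(n)) {
      if (!is.finite(ent$rp_mv[i]) || abs(ent$rp_mv[i]) > 1000)
        problems <- c(problems, sprintf(
          "row %d (%s): rp_mv outside [-1000, 1000] mV", i, ent$entry_id[i]))
      if (!is.finite(ent$ph[i]) || ent$ph[i] < 0 || ent$ph[i] > 14)
        problems <- c(problems, sprintf(
          "row %d (%s): pH outside [0, 14]", i, ent$entry_id[i]))
      if (!(ent$class[i] %in% .known_classes))
        problems <- c(problems, sprintf(
          "row %d (%s): unknown protein class '%s'", i, ent$entry_id[i],
          ent$class[i]))
    }
  }
  if (length(problems))
    stop("data set validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  smry <- list(n = n, per_class = table(ent$class),
               rp_range = range(ent$rp_mv),
               n_proteins = length(unique(ent$protein_id)))
  attr(ent, "summary") <- smry
  if (verbose) {
    message("loaded ", n, " entries, ", smry$n_proteins, " proteins; RP range [",
            smry$rp_range[1], ", ", smry$rp_range[2], "] mV")
    message(paste(sprintf("  %s: %d", names(smry$per_class),
                          as.integer(smry$per_class)), collapse = "\n"))
  }
  ent
}

.resolve_structures <- function(entries, structures) {
  ids <- unique(entries$structure)
  if (is.list(structures)) {
    missing <- setdiff(ids, names(structures))
    if (length(missing))
      stop("unresolvable structures: ", paste(missing, collapse = ", "))
    return(structures[ids])
  }
  dir <- if (is.character(structures)) structures else "."
  out <- list()
  missing <- character()
  for (id in ids) {
    cand <- c(id, file.path(dir, id), file.path(dir, paste0(id, ".pdb")))
    hit <- cand[file.exists(cand)]
    if (!length(hit)) { missing <- c(missing, id); next }
    out[[id]] <- read_pdb(hit[1])
  }
  if (length(missing))
    stop("unresolvable structures: ", paste(missing, collapse = ", "))
  out
}

#' Build a design matrix from entries and structures
#'
#' Featurizes every entry's structure at its cofactor site and assembles the
#' entry-aligned design matrix, target vector and parent-protein grouping
#' vector. Structure featurization is cached per structure: entries sharing a
#' structure differ only in their condition columns (pH, and technique in the
#' variant schema).
#'
#' @param entries entry table as returned by [load_dataset()] (or the
#'   `entries` element of [make_synthetic_dataset()]).
#' @param structures named list of `fes_structure` objects (names = the
#'   `structure` refs in `entries`) or a directory containing
#'   `<structure>.pdb` files.
#' @param strategy `"A"` (fixed radii) or `"B"` (all radii).
#' @param r1,r2 radii for strategy A.
#' @param technique include the one-hot technique block (variant schema).
#' @param table residue property table.
#' @param rule residue-to-region assignment rule.
#' @return list of class `fes_design`: `X` (matrix, schema-named columns),
#'   `y` (rp_mv), `groups` (parent protein id per row), `classes`, `entries`,
#'   `schema`.
#' @export
build_design_matrix <- function(entries, structures, strategy = c("A", "B"),
                                r1 = 11, r2 = 4, technique = FALSE,
                                table = aa_properties(), rule = "any") {
  strategy <- match.arg(strategy)
  structures <- .resolve_structures(entries, structures)
  schema <- if (strategy == "A")
    feature_schema("A", r1 = r1, r2 = r2, technique = technique)
  else feature_schema("B", technique = technique)
  cache <- new.env(parent = emptyenv())
  base_row <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    s <- structures[[id]]
    e <- entries[match(id, entries$structure), ]
    selector <- if (!is.na(e$site_resno))
      list(chain = e$site_chain, resno = e$site_resno) else NULL
    site <- detect_cluster_sites(s, selector = selector)[[1]]
    v <- if (strategy == "A")
      featurize(s, site, r1 = r1, r2 = r2, ph = 7, schema = schema,
                table = table, rule = rule)
    else featurize_all_radii(s, site, ph = 7, schema = schema, table = table,
                             rule = rule)
    cache[[id]] <- v
    v
  }
  X <- matrix(NA_real_, nrow = nrow(entries), ncol = nrow(schema),
              dimnames = list(entries$entry_id, schema$name))
  for (i in seq_len(nrow(entries))) {
    v <- tryCatch(base_row(entries$structure[i]),
                  error = function(e) stop("featurization failed for entry ",
                                           entries$entry_id[i], ": ",
                                           conditionMessage(e), call. = FALSE))
    v["Global.pH"] <- entries$ph[i]
    if (isTRUE(technique)) {
      oh <- .one_hot_technique(entries$technique[i])
      v[names(oh)] <- oh
    }
    X[i, ] <- v
  }
  structure(list(X = X, y = entries$rp_mv, groups = entries$protein_id,
                 classes = entries$class, entries = entries, schema = schema),
            class = "fes_design")
}

#' @exportS3Method base::print
print.fes_design <- function(x, ...) {
  cat("<fes_design> ", nrow(x$X), " entries x ", ncol(x$X), " features (strategy ",
      attr(x$schema, "strategy"), ")\n", sep = "")
  cat("  ", length(unique(x$groups)), " parent proteins; RP range [",
      min(x$y), ", ", max(x$y), "] mV\n", sep = "")
  invisible(x)
}
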