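#' Physicochemical property table for the 20 canonical amino acids
#'
#' The frozen per-residue property table that all region descriptors are summed
#' from. Each row is one canonical residue (three-letter code); columns are
#' eight 0/1 class flags and eighteen numeric properties drawn from standard
#' published scales:
#'
#' * `hydropathy` — Kyte–Doolittle hydropathy index.
#' * `volume` — residue volume (Zamyatnin), cubic Angstrom.
#' * `bulkiness` — side-chain steric hindrance (Zimmerman bulkiness).
#' * `flexibility` — backbone flexibility index (Bhaskaran–Ponnuswamy).
#' * `polarity` — Grantham polarity.
#' * `pi` — isoelectric point of the free amino acid (Zimmerman).
#' * `mass` — average residue mass, Da.
#' * `net.charge` — formal side-chain charge at neutral pH (Asp/Glu -1,
#'   Lys/Arg +1, His +0.1).
#' * `hb.don`, `hb.acc` — side-chain hydrogen-bond donor / acceptor group counts.
#' * `sc.n`, `sc.o`, `sc.s` — side-chain nitrogen / oxygen / sulfur atom counts.
#' * `sasa` — maximum solvent-accessible surface area (theoretical, Tien et al.),
#'   square Angstrom.
#' * `helix`, `sheet`, `turn` — Chou–Fasman secondary-structure propensities.
#' * `steric.flex` — composite of steric hindrance and backbone flexibility:
#'   the sum of the z-scores (over the 20 residues) of `bulkiness` and
#'   `flexibility`. This is the composite descriptor family that dominates the
#'   attribution analysis on real Fe-S data.
#'
#' Class flags follow the grouping used throughout the package: cysteine is a
#' neutral polar residue; histidine, lysine and arginine are basic/positively
#' charged. Flags are not a partition (His is both aromatic and basic).
#'
#' The table is a versioned constant, not a configuration knob; a drop-in
#' replacement table with identical columns may be passed to the descriptor
#' functions for exact replication against other parameterizations.
#'
#' @return A data.frame with 20 rows (rownames = three-letter codes) and the
#'   columns described above.
#' @examples
#' tab <- aa_properties()
#' tab["CYS", c("polar.neutral", "sc.s")]
#' @export
aa_properties <- function() {
  .aa_property_table
}

# Row order: alphabetical by three-letter code.
.aa_build_table <- function() {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
          "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
  one <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  flag <- function(members) as.numeric(one %in% members)
  tab <- data.frame(
    row.names = aa,
    one.letter = one,
    # class flags: Cys polar-neutral; His/Lys/Arg basic
    polar.neutral = flag(c("S", "T", "N", "Q", "C", "Y")),
    hydrophobic   = flag(c("A", "V", "L", "I", "M", "F", "W")),
    aromatic      = flag(c("F", "W", "Y", "H")),
    basic         = flag(c("K", "R", "H")),
    acidic        = flag(c("D", "E")),
    is.cys        = flag("C"),
    is.his        = flag("H"),
    glypro        = flag(c("G", "P")),
    hydropathy = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                   3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    volume = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2,
               166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8,
               193.6, 140.0),
    bulkiness = c(11.50, 14.28, 12.82, 11.68, 13.46, 14.45, 13.57, 3.40, 13.69,
                  21.40, 21.40, 15.71, 16.25, 19.80, 17.43, 9.47, 15.77, 21.67,
                  18.03, 21.57),
    flexibility = c(0.357, 0.529, 0.463, 0.511, 0.346, 0.493, 0.497, 0.544,
                    0.323, 0.462, 0.365, 0.466, 0.295, 0.314, 0.509, 0.507,
                    0.444, 0.305, 0.420, 0.386),
    polarity = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
                 4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    pi = c(6.00, 10.76, 5.41, 2.77, 5.05, 5.65, 3.22, 5.97, 7.59, 6.02,
           5.98, 9.74, 5.74, 5.48, 6.30, 5.68, 5.66, 5.89, 5.66, 5.96),
    mass = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12, 57.05,
             137.14, 113.16, 113.16, 128.17, 131.19, 147.18, 97.12, 87.08,
             101.10, 186.21, 163.18, 99.13),
    net.charge = c(0, 1, 0, -1, 0, 0, -1, 0, 0.1, 0,
                   0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    hb.don = c(0, 3, 1, 0, 1, 1, 0, 0, 1, 0,
               0, 1, 0, 0, 0, 1, 1, 1, 1, 0),
    hb.acc = c(0, 0, 1, 2, 1, 1, 2, 0, 1, 0,
               0, 0, 1, 0, 0, 1, 1, 0, 1, 0),
    sc.n = c(0, 3, 1, 0, 0, 1, 0, 0, 2, 0,
             0, 1, 0, 0, 0, 0, 0, 1, 0, 0),
    sc.o = c(0, 0, 1, 2, 0, 1, 2, 0, 0, 0,
             0, 0, 0, 0, 0, 1, 1, 0, 1, 0),
    sc.s = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0,
             0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
    sasa = c(129, 274, 195, 193, 167, 225, 223, 104, 224, 197,
             201, 236, 224, 240, 159, 155, 172, 285, 263, 174),
    helix = c(1.42, 0.98, 0.67, 1.01, 0.70, 1.11, 1.51, 0.57, 1.00, 1.08,
              1.21, 1.16, 1.45, 1.13, 0.57, 0.77, 0.83, 1.08, 0.69, 1.06),
    sheet = c(0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37, 0.75, 0.87, 1.60,
              1.30, 0.74, 1.05, 1.38, 0.55, 0.75, 1.19, 1.37, 1.47, 1.70),
    turn = c(0.66, 0.95, 1.56, 1.46, 1.19, 0.98, 0.74, 1.56, 0.95, 0.47,
              0.59, 1.01, 0.60, 0.60, 1.52, 1.43, 0.96, 0.96, 1.14, 0.50),
    stringsAsFactors = FALSE
  )
  z <- function(x) (x - mean(x)) / stats::sd(x)
  tab$steric.flex <- z(tab$bulkiness) + z(tab$flexibility)
  tab
}

.aa_property_table <- .aa_build_table()

# canonical three-letter codes, alphabetical
.aa_codes <- rownames(.aa_property_table)

# numeric property columns aggregated in region blocks (steric.flex handled
# separately: sum-only composite)
.aa_numeric_props <- c("hydropathy", "volume", "bulkiness", "flexibility",
                       "polarity", "pi", "mass", "net.charge", "hb.don",
                       "hb.acc", "sc.n", "sc.o", "sc.s", "sasa", "helix",
                       "sheet", "turn")

.aa_class_flags <- c("polar.neutral", "hydrophobic", "aromatic", "basic",
                     "acidic", "is.cys", "is.his", "glypro")

#' Validate a drop-in residue property table
#'
#' Checks that a replacement table covers all 20 canonical residues and all
#' columns the descriptor schema aggregates, with 0/1 class flags.
#'
#' @param table candidate data.frame, rownames = three-letter codes.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
check_property_table <- function(table) {
  need <- c(.aa_class_flags, .aa_numeric_props, "steric.flex")
  if (!all(.aa_codes %in% rownames(table)))
    stop("property table must cover all 20 canonical residues")
  miss <- setdiff(need, colnames(table))
  if (length(miss))
    stop("property table lacks columns: ", paste(miss, collapse = ", "))
  flags <- as.matrix(table[.aa_codes, .aa_class_flags])
  if (!all(flags %in% c(0, 1)))
    stop("class flags must be 0/1")
  if (anyNA(table[.aa_codes, need]))
    stop("property table contains missing values")
  invisible(table)
}
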