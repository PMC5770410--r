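# Bundled reference tables: per-element vdW radii and Lennard-Jones
# parameters, per-residue heavy-atom composition, connectivity, united-atom
# partial charges (hydrogen charges folded into the parent heavy atom,
# pH 7 protonation: ASP/GLU deprotonated, LYS/ARG protonated, HIS neutral),
# side-chain internal coordinates and chi-angle atom quads.
#
# The geometry tables were derived once from ideal residue coordinates and
# shipped as plain CSV under extdata; they are package constants.

.pf_cache <- new.env(parent = emptyenv())

pf_table <- function(name) {
  if (!is.null(.pf_cache[[name]])) return(.pf_cache[[name]])
  path <- system.file("extdata", paste0(name, ".csv"), package = "pepfab")
  if (path == "") stop("bundled table not found: ", name)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .pf_cache[[name]] <- tab
  tab
}

#' Bundled per-element parameters
#'
#' van der Waals radii (Bondi-style, Angstrom) and Lennard-Jones well
#' parameters (epsilon in kcal/mol, rmin/2 in Angstrom) per element symbol.
#'
#' @return data.frame with columns element, vdw_radius, lj_rmin2, lj_eps.
#' @export
element_table <- function() pf_table("elements")

#' Bundled residue templates
#'
#' Heavy-atom composition, intra-residue connectivity, united-atom partial
#' charges and side-chain internal coordinates for the 20 standard residues.
#'
#' @param what one of "atoms", "bonds", "charges", "zmat", "chi".
#' @return data.frame; see the extdata CSV headers for columns.
#' @export
residue_table <- function(what = c("atoms", "bonds", "charges", "zmat", "chi")) {
  what <- match.arg(what)
  switch(what,
         atoms = pf_table("residue_atoms"),
         bonds = pf_table("residue_bonds"),
         charges = pf_table("charges"),
         zmat = pf_table("sidechain_zmat"),
         chi = pf_table("chi_defs"))
}

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Convert a one-letter sequence to three-letter residue codes
#' @param sequence single string of one-letter residue codes.
#' @return character vector of three-letter codes.
#' @export
seq_to_three <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, names(AA1))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  unname(AA1[letters1])
}

vdw_radius_of <- function(element) {
  et <- element_table()
  r <- et$vdw_radius[match(element, et$element)]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(element[is.na(r)]), collapse = ","),
            "; using 1.7 A")
    r[is.na(r)] <- 1.7
  }
  r
}

charge_of <- function(res, atom) {
  ct <- residue_table("charges")
  q <- ct$charge[match(paste(res, atom), paste(ct$res, ct$atom))]
  q
}

element_from_name <- function(name) {
  # PDB atom-name heuristic for files lacking the element column
  if (length(name) == 0) return(character(0))
  n <- gsub("[0-9']", "", trimws(name))
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")
  out <- ifelse(toupper(n) %in% two, toupper(n), substr(n, 1, 1))
  substr(out, 1, 1) <- toupper(substr(out, 1, 1))
  out
}
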