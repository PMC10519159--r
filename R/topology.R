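#' Build and validate a system topology
#'
#' A topology is a data frame with one row per atom and columns
#' `atom_id`, `name`, `element`, `residue_name`, `residue_index`,
#' `chain_id`, `molecule_id`, `species` (one of protein/water/cosolvent),
#' `role` (main_chain/side_chain/solvent), `charge` (e), `lj_sigma` (nm),
#' `lj_epsilon` (kcal/mol). `kb_topology()` fills defaults, checks the
#' invariants and returns the validated data frame.
#'
#' @param atoms data frame with at least `name`, `residue_name`,
#'   `residue_index`, `species`; missing columns are filled with defaults
#'   (`charge` 0, `lj_sigma` 0, `lj_epsilon` 0, `chain_id` "A",
#'   `molecule_id` from residue/species grouping, `role` from species).
#' @return Validated topology data frame (class `kb_topology` prepended).
#' @export
kb_topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "residue_name", "residue_index", "species")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("topology is missing required columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0L) stop("topology has no atoms")
  if (is.null(atoms$atom_id)) atoms$atom_id <- seq_len(n)
  if (is.null(atoms$element)) atoms$element <- substr(atoms$name, 1L, 1L)
  if (is.null(atoms$chain_id)) atoms$chain_id <- "A"
  if (is.null(atoms$molecule_id)) {
    # non-protein: one molecule per residue index within species;
    # protein: one molecule per chain
    key <- ifelse(atoms$species == "protein",
                  paste0("P:", atoms$chain_id),
                  paste0(atoms$species, ":", atoms$residue_index))
    atoms$molecule_id <- match(key, unique(key))
  }
  if (is.null(atoms$role))
    atoms$role <- ifelse(atoms$species == "protein", "side_chain", "solvent")
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$lj_sigma)) atoms$lj_sigma <- 0
  if (is.null(atoms$lj_epsilon)) atoms$lj_epsilon <- 0

  if (!all(atoms$species %in% c("protein", "water", "cosolvent")))
    stop("species must be one of protein/water/cosolvent")
  if (!all(atoms$role %in% c("main_chain", "side_chain", "solvent")))
    stop("role must be one of main_chain/side_chain/solvent")
  if (any(!is.finite(atoms$charge))) stop("non-finite charge in topology")
  if (any(atoms$lj_sigma < 0)) stop("negative lj_sigma in topology")
  if (any(atoms$lj_epsilon < 0)) stop("negative lj_epsilon in topology")
  bad <- (atoms$role == "solvent") != (atoms$species != "protein")
  if (any(bad))
    stop("role 'solvent' must be assigned exactly to non-protein atoms (",
         sum(bad), " violations)")
  class(atoms) <- unique(c("kb_topology", class(atoms)))
  atoms
}

#' Default main-chain atom names
#'
#' Backbone heavy atoms N/CA/C/O, terminal OXT, the amide hydrogen(s)
#' H/H1/H2/H3 and the alpha hydrogens HA/HA1/HA2/HA3 (glycine has two).
#' The backbone atom set is a convention, not a property of the structure,
#' so it is a configurable default.
#'
#' @return Character vector of atom names.
#' @export
main_chain_names <- function() {
  c("N", "CA", "C", "O", "OXT",
    "H", "H1", "H2", "H3", "HA", "HA1", "HA2", "HA3")
}

#' Assign main-chain / side-chain / solvent roles
#'
#' Every protein atom whose name is in `main_chain` becomes `main_chain`,
#' every other protein atom `side_chain`; all non-protein atoms get role
#' `solvent`. The assignment is total and deterministic.
#'
#' @param topology topology data frame (see [kb_topology()]).
#' @param main_chain character vector of atom names treated as backbone;
#'   defaults to [main_chain_names()].
#' @param side_chain optional character vector of recognized side-chain
#'   names, used only under `strict = TRUE`.
#' @param strict if TRUE, protein atom names found in neither list raise an
#'   error listing the offending names.
#' @return Topology with the `role` column (re)assigned.
#' @examples
#' top <- kb_topology(data.frame(
#'   name = c("N", "CA", "CB", "HA2"), residue_name = "ALA",
#'   residue_index = 1, species = "protein"))
#' classify_roles(top)$role
#' @export
classify_roles <- function(topology, main_chain = main_chain_names(),
                           side_chain = NULL, strict = FALSE) {
  topology <- kb_topology(topology)
  prot <- topology$species == "protein"
  if (strict) {
    known <- c(main_chain, side_chain)
    unknown <- setdiff(unique(topology$name[prot]), known)
    if (length(unknown))
      stop("unmapped protein atom names in strict mode: ",
           paste(unknown, collapse = ", "))
  }
  topology$role[prot] <- ifelse(topology$name[prot] %in% main_chain,
                                "main_chain", "side_chain")
  topology$role[!prot] <- "solvent"
  topology
}

#' System composition of a binary-solvent box
#'
#' Component labels follow the preferential-binding convention: water = 1,
#' protein = 2, cosolvent = 3. `rho3` is the cosolvent number density in
#' nm^-3; `molarity` the same in mol/L; `mole_fraction` is
#' cosolvent/(cosolvent + water) on a molecule basis.
#'
#' @param n_water,n_cosolvent,n_protein_molecules molecule counts.
#' @param box_volume box volume in nm^3.
#' @return Object of class `system_composition`.
#' @examples
#' # helix-dimer TFE box: 15310 water + 626 TFE -> mole fraction 0.039
#' system_composition(15310, 626, box_volume = 8.1^3)$mole_fraction
#' @export
system_composition <- function(n_water, n_cosolvent, box_volume,
                               n_protein_molecules = 1L) {
  stopifnot(n_water >= 0, n_cosolvent >= 0, is.numeric(box_volume))
  if (!is.finite(box_volume) || box_volume <= 0)
    stop("box_volume must be positive and finite")
  rho3 <- n_cosolvent / box_volume
  nf <- n_water + n_cosolvent
  structure(list(
    n_water = n_water,
    n_cosolvent = n_cosolvent,
    n_protein_molecules = n_protein_molecules,
    box_volume = box_volume,
    rho3 = rho3,
    molarity = molarity_from_density(rho3),
    mole_fraction = if (nf > 0) n_cosolvent / nf else 0
  ), class = "system_composition")
}

#' Composition of a topology + frame
#'
#' Counts molecules of each species in the topology and combines them with
#' the frame's box volume into a [system_composition()].
#'
#' @param topology topology data frame.
#' @param frame frame (list with `box`, `coords`), or NULL if `box` given.
#' @param box orthorhombic box edge lengths (nm), used when `frame` is NULL.
#' @return `system_composition` object.
#' @export
composition <- function(topology, frame = NULL, box = NULL) {
  topology <- kb_topology(topology)
  if (is.null(box)) {
    if (is.null(frame)) stop("either a frame or box edge lengths required")
    box <- frame$box
  }
  stopifnot(length(box) == 3L)
  if (any(!is.finite(box)) || any(box <= 0) || prod(box) == 0)
    stop("box volume must be positive")
  nmol <- function(sp) length(unique(topology$molecule_id[topology$species == sp]))
  system_composition(n_water = nmol("water"),
                     n_cosolvent = nmol("cosolvent"),
                     box_volume = prod(box),
                     n_protein_molecules = nmol("protein"))
}

#' @export
print.system_composition <- function(x, ...) {
  cat(sprintf(
    "System composition: %d water, %d cosolvent, %d protein molecule(s)\n",
    x$n_water, x$n_cosolvent, x$n_protein_molecules))
  cat(sprintf("  box volume %.4g nm^3 | rho3 %.5g nm^-3 | [Co-sol] %.4g M | x3 %.4g\n",
              x$box_volume, x$rho3, x$molarity, x$mole_fraction))
  invisible(x)
}
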