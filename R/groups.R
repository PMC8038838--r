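#' @title Particle-group classification
#' @description Atoms are classified into the particle groups the contact
#'   statistics are computed against: \code{protein}, \code{water},
#'   \code{lipid_tail} (aliphatic acyl-chain carbons only),
#'   \code{lipid_other} (head groups, glycerol, tail hydrogens),
#'   \code{ion}, \code{ligand} (free amino acids outside the protein
#'   chain) and \code{other}.
#' @name memtraj-groups
NULL

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
            "SER", "THR", "TRP", "TYR", "VAL")

#' Build a selection specification
#'
#' An ordered rule list mapping residue-name / atom-name / element patterns
#' (regular expressions, matched against trimmed names) to group roles.
#' The first matching rule wins; unmatched atoms keep the role
#' \code{"other"}.
#'
#' @param rules list of rules; each rule is a list with optional elements
#'   \code{residue_name}, \code{atom_name}, \code{element} (regex) and a
#'   mandatory \code{role}
#' @return object of class \code{SelectionSpec}
#' @export
selection_spec <- function(rules) {
  if (length(rules) == 0) stop("selection spec must contain at least one rule")
  roles <- c("protein", "water", "lipid_tail", "lipid_other", "ion",
             "ligand", "other")
  for (r in rules) {
    if (is.null(r$role) || !(r$role %in% roles)) {
      stop("every rule needs a role in: ", paste(roles, collapse = ", "))
    }
  }
  structure(list(rules = rules), class = "SelectionSpec")
}

#' Default selection specification
#'
#' Covers the components of a typical protein/bilayer simulation: TIP3-style
#' water, K+/Na+/Cl- ions, PE/PG/PC/cardiolipin lipids (acyl-chain carbons
#' \code{C2x}/\code{C3x} as \code{lipid_tail}, the rest of the lipid as
#' \code{lipid_other}) and standard amino-acid residues as protein. Free
#' amino acids are reassigned to \code{ligand} afterwards by
#' \code{\link{assign_groups}}.
#'
#' @param tail_hydrogens include tail hydrogens in \code{lipid_tail}
#'   (default FALSE: "aliphatic carbons" only)
#' @return SelectionSpec
#' @export
default_selection_spec <- function(tail_hydrogens = FALSE) {
  lip <- "^(POP[ECGS]|TMCL2?|CARD|DPP[CE]|DOP[CE])$"
  rules <- list(
    list(residue_name = "^(SOL|HOH|WAT|TIP3?P?)$", role = "water"),
    list(residue_name = "^(K|POT|NA|SOD|CL|CLA)$", role = "ion"),
    list(residue_name = lip, atom_name = "^C[23][0-9]+$", element = "^C$",
         role = "lipid_tail")
  )
  if (tail_hydrogens) {
    rules <- append(rules, list(
      list(residue_name = lip, atom_name = "^H[0-9]+[RSTXYZ]$",
           role = "lipid_tail")), after = 4)
  }
  rules <- c(rules, list(
    list(residue_name = lip, role = "lipid_other"),
    list(residue_name = paste0("^(", paste(AMINO3, collapse = "|"), ")$"),
         role = "protein")
  ))
  selection_spec(rules)
}

# 1-based atom row of a named atom in residue-table row `row` (NA if absent)
atom_in_residue <- function(system, row, name) {
  res <- system$residues[row, ]
  idx <- (res$first:res$last) + 1L
  hit <- idx[system$atoms$name[idx] == name]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

rule_matches <- function(rule, atoms) {
  ok <- rep(TRUE, nrow(atoms))
  if (!is.null(rule$residue_name)) {
    ok <- ok & grepl(rule$residue_name, atoms$residue_name)
  }
  if (!is.null(rule$atom_name)) ok <- ok & grepl(rule$atom_name, atoms$name)
  if (!is.null(rule$element)) ok <- ok & grepl(rule$element, atoms$element)
  ok
}

#' Assign group roles to every atom
#'
#' Applies the selection rules in order (first match wins), then
#' disambiguates free amino-acid ligands from protein residues: any
#' standalone single-residue stretch of an amino-acid name (its own chain,
#' or flanked by non-protein residues) is relabelled \code{ligand}, since a
#' free amino acid such as L-alanine is chemically identical to its
#' in-chain counterpart.
#'
#' When coordinates are available (a \code{Frame} attached to the system,
#' or passed as \code{frame}), peptide-bond continuity (C(i)-N(i+1)
#' distance below 0.2 nm) refines the chain test, which matters for GRO
#' input where chain identifiers do not exist.
#'
#' @param system MolecularSystem
#' @param spec SelectionSpec (default \code{\link{default_selection_spec}})
#' @param frame optional Frame used for the peptide-bond continuity test
#' @return MolecularSystem with \code{group_role} filled in
#' @export
assign_groups <- function(system, spec = default_selection_spec(),
                          frame = attr(system, "frame")) {
  atoms <- system$atoms
  role <- rep("other", nrow(atoms))
  assigned <- rep(FALSE, nrow(atoms))
  for (rule in spec$rules) {
    ok <- rule_matches(rule, atoms) & !assigned
    if (!any(rule_matches(rule, atoms))) {
      warning("selection rule for role '", rule$role, "' matches no atoms")
    }
    role[ok] <- rule$role
    assigned <- assigned | ok
  }
  atoms$group_role <- role
  # ligand disambiguation on residues currently labelled protein: a
  # residue linked to no protein neighbour is a free amino acid
  res <- system$residues
  res_role <- role[res$first + 1L]
  is_prot <- res_role == "protein"
  if (any(is_prot)) {
    n <- nrow(res)
    linked <- logical(max(0, n - 1))
    for (i in seq_len(n - 1)) {
      l <- res$chain[i] == res$chain[i + 1] && is_prot[i] && is_prot[i + 1]
      if (l && !is.null(frame)) {
        ci <- atom_in_residue(system, i, "C")
        ni <- atom_in_residue(system, i + 1L, "N")
        l <- !is.na(ci) && !is.na(ni) &&
          sqrt(sum((frame$coordinates[ci, ] -
                      frame$coordinates[ni, ])^2)) < 0.2
      }
      linked[i] <- l
    }
    lone <- is_prot & !c(FALSE, linked) & !c(linked, FALSE)
    for (ri in which(lone)) {
      idx <- (res$first[ri]:res$last[ri]) + 1L
      atoms$group_role[idx] <- "ligand"
    }
  }
  out <- system
  out$atoms <- atoms
  out$n_protein_residues <- sum(atoms$group_role[res$first + 1L] == "protein")
  out
}

#' Read a selection specification from a YAML file
#'
#' The file holds a top-level \code{rules:} list; each entry may give
#' \code{residue_name}, \code{atom_name}, \code{element} and must give
#' \code{role}.
#'
#' @param path YAML file path
#' @return SelectionSpec
#' @export
read_selection_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$rules)) stop("selection YAML must contain a 'rules' list")
  selection_spec(y$rules)
}
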