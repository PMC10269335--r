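#' Partial-charge set for a residue or fragment
#'
#' An ordered map from atom name to partial charge in elementary-charge
#' units (e). Atom names must be unique within a set; charges are carried
#' at full input precision (rounding happens only at file-write time, see
#' [write_charge_table()]).
#'
#' @param charges Named numeric vector (names = atom names), or a data
#'   frame with columns `atom` and `charge`.
#' @param group_id Optional label for the residue/fragment.
#' @return An object of class `charge_set`.
#' @export
#' @examples
#' cs <- charge_set(c(CG = -0.02, HG = 0.09, `N2'` = -0.33))
#' net_charge(cs)
charge_set <- function(charges = numeric(0), group_id = "") {
  if (is.data.frame(charges)) {
    stopifnot(all(c("atom", "charge") %in% names(charges)))
    atoms <- as.character(charges$atom); vals <- as.numeric(charges$charge)
  } else {
    atoms <- names(charges) %||% character(0)
    vals <- as.numeric(charges)
  }
  if (length(vals) && (length(atoms) != length(vals) || any(!nzchar(atoms))))
    stop_("every charge needs a non-blank atom name")
  if (anyDuplicated(atoms)) stop_("duplicate atom name in charge set")
  if (any(!is.finite(vals))) stop_("non-finite charge")
  structure(list(atom = atoms, charge = vals, group_id = group_id),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("Charge set%s: %d atoms, net %+.4f e\n",
              if (nzchar(x$group_id)) paste0(" '", x$group_id, "'") else "",
              length(x$atom), net_charge(x)))
  if (length(x$atom))
    print(data.frame(atom = x$atom, charge = x$charge), row.names = FALSE)
  invisible(x)
}

#' @export
length.charge_set <- function(x) length(x$atom)

#' Net charge of a charge set
#'
#' @param set A [charge_set()].
#' @return Sum of all partial charges, in e. Empty set gives 0.
#' @export
net_charge <- function(set) {
  stopifnot(inherits(set, "charge_set"))
  if (length(set$charge) == 0L) return(0)
  sum(set$charge)
}

charge_index <- function(set, atom) {
  i <- match(atom, set$atom)
  if (is.na(i)) stop_(sprintf("atom '%s' not present in charge set", atom))
  i
}

#' Aggregate a substituted hydrogen's charge onto its carbon
#'
#' When a hydrogen on a carbon is replaced by a substituent, the standard
#' CHARMM bookkeeping folds the hydrogen's +0.09 e partial charge onto the
#' carbon instead of discarding it, so the group's net charge is
#' conserved exactly. The hydrogen's entry is removed; the carbon's
#' charge is incremented by the removed hydrogen's charge; everything
#' else is untouched.
#'
#' @param set A [charge_set()] containing both atoms.
#' @param hydrogen,carbon Atom names.
#' @return A new `charge_set` without the hydrogen entry.
#' @export
#' @examples
#' cs <- charge_set(c(CG = -0.02, HG = 0.09))
#' aggregate_hydrogen_charge(cs, "HG", "CG")  # CG becomes 0.07 e
aggregate_hydrogen_charge <- function(set, hydrogen, carbon) {
  stopifnot(inherits(set, "charge_set"))
  ih <- charge_index(set, hydrogen)
  ic <- charge_index(set, carbon)
  if (ih == ic) stop_("hydrogen and carbon must be distinct atoms")
  set$charge[ic] <- set$charge[ic] + set$charge[ih]
  set$atom <- set$atom[-ih]
  set$charge <- set$charge[-ih]
  set
}

#' Repair the net charge of a group through one atom
#'
#' Adjusts the named atom's partial charge by exactly
#' `target_net - net_charge(set)` so the set's net charge becomes
#' `target_net`; all other entries are untouched. Applying it a second
#' time is a zero adjustment. This is the neutrality repair used when
#' charge edits leave a residue slightly off its intended integer charge
#' (e.g. absorbing a +0.03 e excess into a backbone nitrogen), and, with
#' `target_net = 0` on a terminal methyl group, the net-zero-methyl
#' convention.
#'
#' @param set A [charge_set()].
#' @param atom Atom name carrying the adjustment.
#' @param target_net Desired net charge in e (default 0).
#' @return A new `charge_set` with net charge exactly `target_net`.
#' @export
#' @examples
#' cs <- charge_set(c(`N2'` = -0.33, C = 0.33, H = 0.03))  # net +0.03
#' repair_neutrality(cs, "N2'", 0)  # N2' becomes -0.36 e
repair_neutrality <- function(set, atom, target_net = 0) {
  stopifnot(inherits(set, "charge_set"), is.finite(target_net))
  i <- charge_index(set, atom)
  set$charge[i] <- set$charge[i] + (target_net - net_charge(set))
  set
}
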