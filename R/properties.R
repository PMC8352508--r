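## Physicochemical property registries, property vectors and z-score
## normalization. A property set fixes the ordered layout of every property
## vector computed under it; all distance-based metrics (pair building, decoy
## selection, DOE, AVE, ML bias) operate on vectors normalized against a
## stated reference population.

ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, P = 30.974, S = 32.067, Cl = 35.453,
                 Br = 79.904, I = 126.904)

#' Molecular weight (average atomic masses, implicit hydrogens included)
#' @param mol a `molecule`.
#' @return numeric.
#' @export
molecular_weight <- function(mol) {
  sum(ATOMIC_MASS[mol$element], na.rm = TRUE) +
    sum(hydrogen_count(mol)) * ATOMIC_MASS[["H"]]
}

#' Hydrogen-bond donor / acceptor counts (Lipinski definitions)
#'
#' Donors: N, O or S atoms bearing at least one hydrogen. Acceptors: all N and
#' O atoms.
#' @param mol a `molecule`.
#' @return integer count.
#' @export
hbd_count <- function(mol) {
  sum(mol$element %in% c("N", "O", "S") & hydrogen_count(mol) > 0L)
}

#' @rdname hbd_count
#' @export
hba_count <- function(mol) sum(mol$element %in% c("N", "O"))

#' Rotatable bond count
#'
#' Acyclic single bonds between two non-terminal heavy atoms, excluding amide
#' C-N bonds.
#' @param mol a `molecule`.
#' @return integer count.
#' @export
rotatable_bonds <- function(mol) {
  if (!n_bonds(mol)) return(0L)
  deg <- atom_degree(mol)
  ring <- ring_bond_mask(mol)
  cnt <- 0L
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_order[k] != 1L || ring[k]) next
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    if (deg[a] < 2L || deg[b] < 2L) next
    if (is_amide_bond(mol, a, b) || is_amide_bond(mol, b, a)) next
    cnt <- cnt + 1L
  }
  cnt
}

is_amide_bond <- function(mol, c_atom, n_atom) {
  if (mol$element[c_atom] != "C" || mol$element[n_atom] != "N") return(FALSE)
  nc <- neighbors(mol, c_atom)
  any(nc$order == 2L & mol$element[nc$atom] == "O")
}

net_charge <- function(mol) sum(mol$charge)
positive_charge_count <- function(mol) sum(mol$charge > 0L)
negative_charge_count <- function(mol) sum(mol$charge < 0L)

descriptor_registry <- function() {
  list(
    mw = molecular_weight,
    logp = logp,
    hbd = hbd_count,
    hba = hba_count,
    rotb = function(m) as.numeric(rotatable_bonds(m)),
    net_charge = function(m) as.numeric(net_charge(m)),
    pos_charge = function(m) as.numeric(positive_charge_count(m)),
    neg_charge = function(m) as.numeric(negative_charge_count(m)),
    aromatic_rings = function(m) as.numeric(count_aromatic_rings(m)),
    ring_count = function(m) as.numeric(count_rings(m)),
    heavy_atoms = function(m) as.numeric(n_atoms(m)),
    c_count = function(m) sum(m$element == "C"),
    n_count = function(m) sum(m$element == "N"),
    o_count = function(m) sum(m$element == "O"),
    s_count = function(m) sum(m$element == "S"),
    f_count = function(m) sum(m$element == "F"),
    cl_count = function(m) sum(m$element == "Cl"),
    halogen_count = function(m) sum(m$element %in% c("F", "Cl", "Br", "I")),
    heteroatom_count = function(m) sum(!m$element %in% c("C", "H")),
    heteroatom_fraction = function(m) mean(!m$element %in% c("C", "H")),
    sp3_fraction = function(m) {
      cs <- which(m$element == "C")
      if (!length(cs)) return(0)
      multi <- unique(c(m$bond_a[m$bond_order > 1L], m$bond_b[m$bond_order > 1L]))
      mean(!(cs %in% multi) & !m$aromatic[cs])
    },
    aromatic_atom_fraction = function(m) mean(m$aromatic),
    largest_ring_size = function(m) {
      rs <- smallest_rings(m)
      if (!length(rs)) 0 else max(vapply(rs, length, integer(1)))
    },
    amide_count = function(m) {
      if (!n_bonds(m)) return(0)
      sum(vapply(seq_len(n_bonds(m)), function(k) {
        a <- m$bond_a[k]; b <- m$bond_b[k]
        m$bond_order[k] == 1L &&
          (is_amide_bond(m, a, b) || is_amide_bond(m, b, a))
      }, logical(1)))
    },
    hydroxyl_count = function(m) {
      sum(m$element == "O" & hydrogen_count(m) > 0L)
    },
    carbonyl_count = function(m) {
      sum(m$bond_order == 2L &
            ((m$element[m$bond_a] == "C" & m$element[m$bond_b] == "O") |
             (m$element[m$bond_b] == "C" & m$element[m$bond_a] == "O")))
    },
    sa_score = sa_score
  )
}

PROPERTY_SET_MEMBERS <- list(
  # the six properties of the original DUD-E construction
  dude6 = c("mw", "logp", "rotb", "hbd", "hba", "net_charge"),
  # the eight properties of the DEKOIS 2.0 construction
  dekois8 = c("mw", "logp", "hbd", "hba", "rotb", "pos_charge", "neg_charge",
              "aromatic_rings"),
  # extended high-dimensional set (27 descriptors incl. synthetic
  # accessibility); membership is user-overridable
  extended27 = c("mw", "logp", "hbd", "hba", "rotb", "net_charge",
                 "pos_charge", "neg_charge", "aromatic_rings", "ring_count",
                 "heavy_atoms", "c_count", "n_count", "o_count", "s_count",
                 "f_count", "cl_count", "halogen_count", "heteroatom_count",
                 "heteroatom_fraction", "sp3_fraction",
                 "aromatic_atom_fraction", "largest_ring_size", "amide_count",
                 "hydroxyl_count", "carbonyl_count", "sa_score")
)

#' Property set registry
#'
#' Built-in registries: `"dude6"` (molecular weight, logP, rotatable bonds,
#' H-bond donors, H-bond acceptors, net formal charge), `"dekois8"` (adds
#' separate positive/negative charge counts and aromatic ring count) and
#' `"extended27"` (a 27-descriptor superset including the synthetic
#' accessibility score). A custom set is built by passing descriptor names
#' from the registry, or named functions.
#'
#' @param name `"dude6"`, `"dekois8"`, `"extended27"`, or a custom name when
#'   `members` is given.
#' @param members optional character vector of registry descriptor names or a
#'   named list of functions (molecule -> numeric).
#' @return object of class `property_set` with elements `name`, `properties`
#'   (named ordered list of functions).
#' @export
property_set <- function(name = c("dude6", "dekois8", "extended27"),
                         members = NULL) {
  reg <- descriptor_registry()
  if (is.null(members)) {
    name <- match.arg(name)
    members <- PROPERTY_SET_MEMBERS[[name]]
  }
  props <- if (is.character(members)) {
    missing <- setdiff(members, names(reg))
    if (length(missing)) stop("unknown descriptors: ", paste(missing, collapse = ", "))
    stats::setNames(reg[members], members)
  } else {
    stopifnot(is.list(members), !is.null(names(members)))
    members
  }
  if (anyDuplicated(names(props))) stop("duplicate property names")
  structure(list(name = name, properties = props), class = "property_set")
}

#' @export
print.property_set <- function(x, ...) {
  cat(sprintf("<property_set '%s'> %d properties: %s\n", x$name,
              length(x$properties), paste(names(x$properties), collapse = ", ")))
  invisible(x)
}

#' Compute a property vector
#'
#' Deterministic: the same molecular graph always yields the same vector. A
#' descriptor failure yields a flagged (all-NA) vector with a warning so the
#' molecule can be excluded downstream.
#'
#' @param mol a `molecule`.
#' @param pset a [property_set()].
#' @return named numeric vector with attribute `schema` (the set name).
#' @export
compute_properties <- function(mol, pset) {
  vals <- tryCatch(
    vapply(pset$properties, function(f) as.numeric(f(mol)), numeric(1)),
    error = function(e) {
      warning("descriptor failure: ", conditionMessage(e), call. = FALSE)
      stats::setNames(rep(NA_real_, length(pset$properties)),
                      names(pset$properties))
    })
  attr(vals, "schema") <- pset$name
  vals
}

#' Property matrix for a list of molecules
#' @param mols list of `molecule` objects.
#' @param pset a [property_set()].
#' @return numeric matrix, one row per molecule, with attribute `schema`.
#' @export
property_matrix <- function(mols, pset) {
  m <- t(vapply(mols, function(mm) {
    v <- compute_properties(mm, pset)
    attributes(v) <- list(names = names(v))
    v
  }, stats::setNames(numeric(length(pset$properties)), names(pset$properties))))
  attr(m, "schema") <- pset$name
  m
}

#' Fit a z-score normalization model
#'
#' Per-property location (mean) and scale (standard deviation) over a
#' reference population. Zero-variance properties are flagged degenerate and
#' their scale clamped to 1 (with a warning) so distances stay finite.
#'
#' @param vectors numeric matrix (rows = molecules) or list of property
#'   vectors sharing a schema.
#' @return object of class `normalization_model` with `center`, `scale`,
#'   `degenerate`, `schema`, `n`.
#' @export
fit_normalization <- function(vectors) {
  m <- if (is.matrix(vectors)) vectors else do.call(rbind, vectors)
  if (nrow(m) < 2L) stop("need at least 2 vectors to fit normalization")
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  degenerate <- !is.finite(scale) | scale < 1e-12
  if (any(degenerate)) {
    warning(sprintf("degenerate (constant) properties clamped: %s",
                    paste(colnames(m)[degenerate], collapse = ", ")),
            call. = FALSE)
    scale[degenerate] <- 1
  }
  structure(list(center = center, scale = scale, degenerate = degenerate,
                 schema = attr(vectors, "schema"), n = nrow(m)),
            class = "normalization_model")
}

#' Apply a normalization model
#' @param m numeric matrix or vector of property values.
#' @param norm a [fit_normalization()] model.
#' @return z-scored matrix/vector.
#' @export
normalize_properties <- function(m, norm) {
  if (is.matrix(m)) {
    sweep(sweep(m, 2L, norm$center, "-"), 2L, norm$scale, "/")
  } else {
    (m - norm$center) / norm$scale
  }
}

#' Euclidean distance between normalized property vectors
#'
#' @param a,b property vectors sharing a schema.
#' @param norm a [fit_normalization()] model.
#' @return non-negative distance (symmetric; 0 iff normalized vectors equal).
#' @export
property_distance <- function(a, b, norm) {
  sa <- attr(a, "schema"); sb <- attr(b, "schema")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb))
    stop("property vector schema mismatch")
  if (length(a) != length(b)) stop("property vector length mismatch")
  sqrt(sum(((a - b) / norm$scale)^2))
}

#' Write / read a property table as CSV
#'
#' First column the molecule name, then one column per property in set order.
#'
#' @param mols list of molecules.
#' @param pset a [property_set()].
#' @param path CSV path.
#' @return (write) the data.frame invisibly; (read) a data.frame.
#' @export
write_property_table <- function(mols, pset, path) {
  m <- property_matrix(mols, pset)
  nm <- vapply(seq_along(mols), function(i) {
    mols[[i]]$name %||% sprintf("mol_%d", i)
  }, character(1))
  df <- data.frame(name = nm, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_property_table
#' @export
read_property_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read a property-set definition from a key/value config file
#'
#' The file carries `name:` and a `members:` list of registry descriptor
#' names, e.g. a custom subset of [property_set()]'s registry.
#'
#' @param path YAML key/value file.
#' @return a [property_set()].
#' @export
read_property_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$members)) stop("property-set config needs a 'members' list")
  property_set(name = cfg$name %||% "custom",
               members = unlist(cfg$members))
}
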