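#' Fold raw fingerprint indices onto a fixed-width bit vector
#'
#' Circular-fingerprint generators emit sparse integer identifiers from a
#' huge hash space. To obtain a fixed-width feature vector each raw index
#' is folded by a modulo calculation: bit `j` of the output is set iff some
#' raw index `i` satisfies `i %% n_bits == j`. The result is a pure
#' function of the set of raw indices — order and multiplicity are
#' irrelevant — and its popcount never exceeds the number of distinct raw
#' indices.
#'
#' @param raw_indices vector of nonnegative integer identifiers.
#' @param n_bits output width (default 4096).
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
#' @examples
#' which(hash_fingerprint_indices(c(5000, 904), 4096) == 1)  # 905 (bit 904)
hash_fingerprint_indices <- function(raw_indices, n_bits = 4096) {
  stopifnot_scalar_number(n_bits, "n_bits", lower = 1)
  out <- integer(n_bits)
  if (length(raw_indices) == 0L) return(out)
  if (!is.numeric(raw_indices) || any(raw_indices < 0) ||
      any(raw_indices != floor(raw_indices))) {
    stop("raw indices must be nonnegative integers", call. = FALSE)
  }
  out[unique(raw_indices %% n_bits) + 1L] <- 1L
  out
}

#' Descriptor configuration
#'
#' Names and fingerprint settings for [compute_descriptors()] and
#' [morgan_fingerprints()]. The default descriptor list has 97 entries —
#' physicochemical properties (molecular weight, logP, TPSA, H-bond
#' donor/acceptor counts, ...) computed by OpenBabel plus constitutional
#' and topological descriptors computed from the molecular graph (element
#' counts and fractions, bond-order and degree distributions, ring
#' statistics, connectivity and shape indices). The list is configurable:
#' any subset or reordering of the built-in names is accepted.
#'
#' @param descriptor_names ordered, duplicate-free character vector of
#'   descriptor names (default [default_descriptors()]).
#' @param fingerprint_bits folded fingerprint width (default 4096).
#' @param fingerprint_radius circular-fingerprint radius (default 2, the
#'   field-standard ECFP4-like choice).
#' @return An object of class `descriptor_config`.
#' @export
descriptor_config <- function(descriptor_names = default_descriptors(),
                              fingerprint_bits = 4096,
                              fingerprint_radius = 2) {
  if (length(descriptor_names) == 0L || anyDuplicated(descriptor_names)) {
    stop("'descriptor_names' must be nonempty and duplicate-free",
         call. = FALSE)
  }
  unknown <- setdiff(descriptor_names, default_descriptors())
  if (length(unknown)) {
    stop("unknown descriptors: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stopifnot_scalar_number(fingerprint_bits, "fingerprint_bits", lower = 1)
  stopifnot_scalar_number(fingerprint_radius, "fingerprint_radius",
                          lower = 0)
  structure(
    list(descriptor_names = as.character(descriptor_names),
         fingerprint_bits = as.integer(fingerprint_bits),
         fingerprint_radius = as.integer(fingerprint_radius)),
    class = "descriptor_config"
  )
}

.ob_props <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
.elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
               "Si", "Se", "As", "Na", "K", "Li", "Mg", "Ca", "Zn", "Fe")
.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904,
                  I = 126.904, B = 10.81, Si = 28.085, Se = 78.971,
                  As = 74.922, Na = 22.99, K = 39.098, Li = 6.94,
                  Mg = 24.305, Ca = 40.078, Zn = 65.38, Fe = 55.845)

#' @rdname descriptor_config
#' @export
default_descriptors <- function() {
  c(
    .ob_props,
    paste0("n_", .elements), paste0("frac_", .elements),
    "n_atoms", "n_bonds", "n_heteroatoms", "frac_hetero",
    "n_halogen", "frac_halogen",
    "n_single", "n_double", "n_triple",
    "frac_single", "frac_double", "frac_triple",
    paste0("n_deg", 1:4), paste0("frac_deg", 1:4),
    "mean_degree", "max_degree",
    "n_rings", "n_ring_atoms", "frac_ring_atoms", "n_ring_bonds",
    paste0("ringbond", 3:8), "largest_ring", "n_components",
    "wiener", "diameter", "graph_radius", "mean_distance",
    "chi0", "chi1", "kappa1", "kappa2", "zagreb1", "zagreb2",
    "n_rotatable", "mean_atomic_mass", "bond_density",
    "hbd_per_atom", "hba_per_atom"
  )
}

require_chemminer <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("featurising SMILES requires the 'ChemmineR' package",
         call. = FALSE)
  }
}

## Parse one SMILES into a light molecular-graph record (heavy atoms only).
## Returns NULL when OpenBabel cannot produce a molecule with atoms.
parse_smiles_graph <- function(smiles, id = "mol") {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) return(NULL)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L) return(NULL)
  elem <- sub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(mol)
  if (is.null(bb) || nrow(bb) == 0L) {
    from <- integer(); to <- integer(); ord <- numeric()
  } else {
    from <- as.integer(bb[, 1]); to <- as.integer(bb[, 2])
    ord <- as.numeric(bb[, 3])
  }
  n <- length(elem)
  adj <- vector("list", n)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], k)
    adj[[to[k]]] <- c(adj[[to[k]]], k)
  }
  deg <- tabulate(c(from, to), nbins = n)
  list(elem = elem, from = from, to = to, order = ord, deg = deg,
       adj = adj, n = n, sdf = sdf)
}

## BFS distances from `start` over the bond list, optionally skipping one
## bond; unreachable atoms get Inf.
bfs_dist <- function(g, start, skip_bond = 0L) {
  d <- rep(Inf, g$n)
  d[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (k in g$adj[[v]]) {
      if (k == skip_bond) next
      w <- if (g$from[k] == v) g$to[k] else g$from[k]
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

## A bond is a ring bond iff its endpoints stay connected without it; the
## smallest ring through it is 1 + that detour length.
ring_bond_sizes <- function(g) {
  vapply(seq_along(g$from), function(k) {
    d <- bfs_dist(g, g$from[k], skip_bond = k)
    if (is.infinite(d[g$to[k]])) NA_real_ else d[g$to[k]] + 1
  }, numeric(1))
}

graph_descriptors <- function(g) {
  n <- g$n
  nb <- length(g$from)
  safe_frac <- function(a, b) if (b > 0) a / b else 0
  elem_counts <- vapply(.elements, function(e) sum(g$elem == e), numeric(1))
  halogen <- sum(elem_counts[c("F", "Cl", "Br", "I")])
  hetero <- n - elem_counts[["C"]]

  ring_sizes <- if (nb > 0) ring_bond_sizes(g) else numeric(0)
  is_ring_bond <- !is.na(ring_sizes)
  ring_atoms <- unique(c(g$from[is_ring_bond], g$to[is_ring_bond]))

  ## all-pairs BFS for Wiener/eccentricity statistics (finite pairs only)
  dists <- lapply(seq_len(n), function(v) bfs_dist(g, v))
  finite_pair <- unlist(lapply(dists, function(d) d[is.finite(d) & d > 0]))
  ecc <- vapply(dists, function(d) {
    f <- d[is.finite(d)]
    if (length(f)) max(f) else 0
  }, numeric(1))
  ## connected components via repeated BFS
  comp <- rep(0L, max(n, 1L)); nc <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      nc <- nc + 1L
      comp[is.finite(dists[[v]])] <- nc
    }
  }

  deg <- g$deg
  p2 <- sum(choose(deg, 2))  # paths of length 2
  chi0 <- sum(1 / sqrt(deg[deg > 0]))
  chi1 <- if (nb > 0) {
    sum(1 / sqrt(deg[g$from] * deg[g$to]))
  } else 0
  kappa1 <- if (nb > 0) n * (n - 1)^2 / nb^2 else 0
  kappa2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0
  rotatable <- sum(!is_ring_bond & g$order == 1 &
                     g$deg[g$from] > 1 & g$deg[g$to] > 1)
  masses <- .atomic_mass[g$elem]
  masses[is.na(masses)] <- 0

  out <- c(
    stats::setNames(elem_counts, paste0("n_", .elements)),
    stats::setNames(elem_counts / n, paste0("frac_", .elements)),
    n_atoms = n, n_bonds = nb,
    n_heteroatoms = hetero, frac_hetero = hetero / n,
    n_halogen = halogen, frac_halogen = halogen / n,
    n_single = sum(g$order == 1), n_double = sum(g$order == 2),
    n_triple = sum(g$order == 3),
    frac_single = safe_frac(sum(g$order == 1), nb),
    frac_double = safe_frac(sum(g$order == 2), nb),
    frac_triple = safe_frac(sum(g$order == 3), nb),
    stats::setNames(vapply(1:4, function(d) sum(deg == d), numeric(1)),
                    paste0("n_deg", 1:4)),
    stats::setNames(vapply(1:4, function(d) sum(deg == d) / n, numeric(1)),
                    paste0("frac_deg", 1:4)),
    mean_degree = mean(deg), max_degree = max(c(deg, 0)),
    n_rings = nb - n + nc,
    n_ring_atoms = length(ring_atoms),
    frac_ring_atoms = length(ring_atoms) / n,
    n_ring_bonds = sum(is_ring_bond),
    stats::setNames(vapply(3:8, function(s) {
      sum(ring_sizes[is_ring_bond] == s)
    }, numeric(1)), paste0("ringbond", 3:8)),
    largest_ring = if (any(is_ring_bond)) max(ring_sizes, na.rm = TRUE) else 0,
    n_components = nc,
    wiener = sum(finite_pair) / 2,
    diameter = max(c(ecc, 0)),
    graph_radius = if (length(ecc)) min(ecc) else 0,
    mean_distance = if (length(finite_pair)) mean(finite_pair) else 0,
    chi0 = chi0, chi1 = chi1, kappa1 = kappa1, kappa2 = kappa2,
    zagreb1 = sum(deg^2), zagreb2 = if (nb > 0) {
      sum(deg[g$from] * deg[g$to])
    } else 0,
    n_rotatable = rotatable,
    mean_atomic_mass = mean(masses),
    bond_density = safe_frac(nb, n)
  )
  out
}

#' Compute molecular descriptors from SMILES
#'
#' Parses each SMILES with OpenBabel (via ChemmineR) and computes the
#' descriptors named in the configuration (by default 97 of them, see
#' [default_descriptors()]). Unparsable SMILES are *not* silently imputed:
#' their rows are dropped from the matrix and reported in the `failures`
#' attribute, because silently zero-filled feature rows would corrupt
#' downstream conformal calibration.
#'
#' @param smiles character vector of SMILES strings.
#' @param config a [descriptor_config()].
#' @param ids optional compound identifiers used as row names.
#' @return Numeric matrix with one row per successfully parsed SMILES and
#'   one column per configured descriptor, with attribute `failures`
#'   (a data frame of index, id, smiles for the failed records).
#' @export
compute_descriptors <- function(smiles, config = descriptor_config(),
                                ids = NULL) {
  require_chemminer()
  if (!inherits(config, "descriptor_config")) {
    stop("'config' must be a descriptor_config", call. = FALSE)
  }
  if (length(smiles) == 0L) stop("no SMILES supplied", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("mol%d", seq_along(smiles))
  rows <- vector("list", length(smiles))
  failed <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    g <- parse_smiles_graph(smiles[i], ids[i])
    if (is.null(g)) {
      failed[i] <- TRUE
      next
    }
    ob <- tryCatch(ChemmineR::propOB(g$sdf), error = function(e) NULL)
    ob_vals <- if (is.null(ob)) {
      stats::setNames(rep(NA_real_, length(.ob_props)), .ob_props)
    } else {
      stats::setNames(as.numeric(ob[1, .ob_props]), .ob_props)
    }
    all_desc <- c(ob_vals, graph_descriptors(g))
    all_desc[["hbd_per_atom"]] <- all_desc[["HBD"]] / all_desc[["n_atoms"]]
    all_desc[["hba_per_atom"]] <- all_desc[["HBA1"]] / all_desc[["n_atoms"]]
    rows[[i]] <- all_desc[config$descriptor_names]
  }
  if (all(failed)) {
    stop("no SMILES could be parsed", call. = FALSE)
  }
  mat <- do.call(rbind, rows[!failed])
  colnames(mat) <- config$descriptor_names
  rownames(mat) <- ids[!failed]
  attr(mat, "failures") <- data.frame(
    index = which(failed), id = ids[failed], smiles = smiles[failed],
    stringsAsFactors = FALSE
  )
  mat
}

## Deterministic integer hash of an integer vector, in [0, 2^31 - 2].
ihash <- function(v) {
  h <- 0
  for (x in v) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  h
}

#' Raw circular-fingerprint identifiers of a molecule
#'
#' Morgan-style iterative neighbourhood hashing on the heavy-atom graph:
#' each atom starts from an invariant built from its element, degree, total
#' bond order and ring membership; at every radius step the invariant is
#' rehashed together with the sorted (bond order, neighbour invariant)
#' pairs. The identifiers collected over radii 0..`radius` are the raw
#' indices subsequently folded by [hash_fingerprint_indices()].
#'
#' @param smiles one SMILES string.
#' @param radius neighbourhood radius (default 2).
#' @return Integer vector of raw identifiers (possibly with duplicates),
#'   or `NULL` when the SMILES cannot be parsed.
#' @export
morgan_indices <- function(smiles, radius = 2) {
  require_chemminer()
  g <- parse_smiles_graph(smiles)
  if (is.null(g)) return(NULL)
  ring_sizes <- if (length(g$from)) ring_bond_sizes(g) else numeric(0)
  ring_atom <- unique(c(g$from[!is.na(ring_sizes)],
                        g$to[!is.na(ring_sizes)]))
  elem_code <- match(g$elem, .elements)
  elem_code[is.na(elem_code)] <- length(.elements) + 1L
  bond_sum <- vapply(seq_len(g$n), function(v) {
    sum(g$order[g$adj[[v]]])
  }, numeric(1))
  inv <- vapply(seq_len(g$n), function(v) {
    ihash(c(elem_code[v], g$deg[v], round(2 * bond_sum[v]),
            as.integer(v %in% ring_atom)))
  }, numeric(1))
  ids <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(g$n), function(v) {
      pairs <- t(vapply(g$adj[[v]], function(k) {
        w <- if (g$from[k] == v) g$to[k] else g$from[k]
        c(round(2 * g$order[k]), inv[w])
      }, numeric(2)))
      if (length(pairs) == 0L) return(inv[v])
      ord <- order(pairs[, 1], pairs[, 2])
      ihash(c(inv[v], t(pairs[ord, , drop = FALSE])))
    }, numeric(1))
    ids <- c(ids, inv)
  }
  as.integer(ids)
}

#' Folded circular fingerprints for a set of SMILES
#'
#' @param smiles character vector of SMILES.
#' @param config a [descriptor_config()] supplying the fingerprint width
#'   and radius.
#' @param ids optional identifiers used as row names.
#' @return Binary matrix (rows = parsed molecules, columns = bits) with a
#'   `failures` attribute as in [compute_descriptors()].
#' @export
morgan_fingerprints <- function(smiles, config = descriptor_config(),
                                ids = NULL) {
  require_chemminer()
  if (length(smiles) == 0L) stop("no SMILES supplied", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("mol%d", seq_along(smiles))
  rows <- vector("list", length(smiles))
  failed <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    raw <- morgan_indices(smiles[i], radius = config$fingerprint_radius)
    if (is.null(raw)) {
      failed[i] <- TRUE
    } else {
      rows[[i]] <- hash_fingerprint_indices(raw, config$fingerprint_bits)
    }
  }
  if (all(failed)) stop("no SMILES could be parsed", call. = FALSE)
  mat <- do.call(rbind, rows[!failed])
  colnames(mat) <- sprintf("bit_%d", seq_len(config$fingerprint_bits) - 1L)
  rownames(mat) <- ids[!failed]
  attr(mat, "failures") <- data.frame(
    index = which(failed), id = ids[failed], smiles = smiles[failed],
    stringsAsFactors = FALSE
  )
  mat
}

#' Read SMILES records from a file
#'
#' Accepts either a CSV with columns `compound_id`, `smiles` and
#' optionally `label`, or a plain SMILES file with one molecule per line
#' (`SMILES` optionally followed by whitespace and an identifier).
#'
#' @param path file path.
#' @return Data frame with columns `compound_id`, `smiles` and, when
#'   present, `label`.
#' @export
read_smiles <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first) && grepl("smiles", tolower(first))) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("compound_id", "smiles") %in% names(df))) {
      stop("SMILES CSV needs 'compound_id' and 'smiles' columns",
           call. = FALSE)
    }
    return(df[, intersect(c("compound_id", "smiles", "label"), names(df))])
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(
    compound_id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L) parts[[i]][2L] else sprintf("mol%d", i)
    }, character(1)),
    smiles = vapply(parts, `[[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
}

#' Structure-standardisation hook
#'
#' Placeholder for an external structure-standardisation step (salt
#' stripping, tautomer canonicalisation). The default is the identity:
#' standardisation pipelines vary by organisation and are best applied
#' before featurisation. Supply any function mapping a character vector of
#' SMILES to a character vector of SMILES.
#'
#' @param smiles character vector of SMILES.
#' @param standardizer function applied to the vector (default identity).
#' @return The standardised SMILES vector.
#' @export
standardize_smiles <- function(smiles, standardizer = identity) {
  standardizer(smiles)
}
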