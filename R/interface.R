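#' Quantify a dimer interface
#'
#' Per-residue burial via SASA difference: for each chain, SASA is computed
#' for the chain alone and in the complex; the per-residue loss
#' (delta-SASA) is the buried area. A residue counts as buried when its
#' delta-SASA exceeds `burial_threshold` (default 1 Angstrom^2, which
#' suppresses sampling noise). The average buried area per monomer is
#' (sum of chain-1 burial + sum of chain-2 burial) / 2. Waters and het
#' groups are excluded throughout; only heavy atoms enter the calculation.
#'
#' @param atoms atom tibble containing both chains.
#' @param chain_a,chain_b the two chain ids (selections must be disjoint).
#' @param burial_threshold Angstrom^2 above which a residue is "buried".
#' @param probe,n_points SASA parameters, see [compute_sasa()].
#' @param contacts also run the geometric contact finders (default `TRUE`).
#' @return An object of class `fl_interface`: list with `per_residue`
#'   (tibble: chain, res_seq, ins, res_name, delta_sasa, buried),
#'   `buried_residues` (named list of two residue tibbles),
#'   `buried_count` (named integer vector), `buried_area_per_monomer`
#'   (named numeric), `buried_area_avg`, `contacts` (tibble, see
#'   [find_salt_bridges()]).
#' @export
interface_report <- function(atoms, chain_a, chain_b, burial_threshold = 1.0,
                             probe = 1.4, n_points = 960, contacts = TRUE) {
  if (chain_a == chain_b) stop("chain selections overlap", call. = FALSE)
  a <- select_atoms(atoms, chain = chain_a, heavy_only = TRUE, drop_het = TRUE)
  b <- select_atoms(atoms, chain = chain_b, heavy_only = TRUE, drop_het = TRUE)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("empty chain selection in interface_report", call. = FALSE)
  ab <- dplyr::bind_rows(a, b)
  sasa_a <- compute_sasa(a, probe = probe, n_points = n_points)
  sasa_b <- compute_sasa(b, probe = probe, n_points = n_points)
  sasa_ab <- compute_sasa(ab, probe = probe, n_points = n_points)
  complex_per_atom <- sasa_ab$per_atom
  alone_per_atom <- c(sasa_a$per_atom, sasa_b$per_atom)
  delta <- alone_per_atom - complex_per_atom   # >= 0 up to sampling noise
  per_res <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(ab[, c("chain", "res_seq", "ins", "res_name")],
                    delta_sasa = delta),
      .data$chain, .data$res_seq, .data$ins, .data$res_name),
    delta_sasa = sum(.data$delta_sasa), .groups = "drop")
  per_res <- dplyr::arrange(per_res, .data$chain, .data$res_seq, .data$ins)
  per_res$buried <- per_res$delta_sasa > burial_threshold
  area <- c(sum(per_res$delta_sasa[per_res$chain == chain_a]),
            sum(per_res$delta_sasa[per_res$chain == chain_b]))
  names(area) <- c(chain_a, chain_b)
  buried <- list(per_res[per_res$buried & per_res$chain == chain_a, ],
                 per_res[per_res$buried & per_res$chain == chain_b, ])
  names(buried) <- c(chain_a, chain_b)
  contact_tbl <- if (contacts) {
    dplyr::bind_rows(find_salt_bridges(atoms, chain_a, chain_b),
                     find_hbonds(atoms, chain_a, chain_b),
                     find_stacking(atoms, chain_a, chain_b))
  } else tibble::tibble()
  structure(list(per_residue = per_res,
                 buried_residues = buried,
                 buried_count = vapply(buried, nrow, integer(1)),
                 buried_area_per_monomer = area,
                 buried_area_avg = mean(area),
                 contacts = contact_tbl,
                 chains = c(chain_a, chain_b),
                 burial_threshold = burial_threshold),
            class = "fl_interface")
}

#' @export
print.fl_interface <- function(x, ...) {
  cat(sprintf("<interface %s|%s> avg buried area %.0f A^2; buried residues %d/%d; %d contacts\n",
              x$chains[1], x$chains[2], x$buried_area_avg,
              x$buried_count[1], x$buried_count[2], nrow(x$contacts)))
  invisible(x)
}

#' @export
tidy.fl_interface <- function(x, ...) x$per_residue

#' @export
glance.fl_interface <- function(x, ...) {
  tibble::tibble(chain_a = x$chains[1], chain_b = x$chains[2],
                 buried_area_avg = x$buried_area_avg,
                 buried_area_a = unname(x$buried_area_per_monomer[1]),
                 buried_area_b = unname(x$buried_area_per_monomer[2]),
                 buried_count_a = unname(x$buried_count[1]),
                 buried_count_b = unname(x$buried_count[2]),
                 n_salt_bridges = sum(x$contacts$kind == "salt_bridge"),
                 n_hbonds = sum(x$contacts$kind %in% c("hbond", "backbone_hbond")),
                 n_stacking = sum(x$contacts$kind == "stacking"))
}

atom_label <- function(atoms, idx) {
  paste0(atoms$chain[idx], ":", atoms$res_name[idx], atoms$res_seq[idx],
         ":", atoms$atom_name[idx])
}

# inter-chain atom pairs within cutoff between two atom subsets
cross_pairs <- function(sub1, sub2, cutoff) {
  if (nrow(sub1) == 0 || nrow(sub2) == 0)
    return(tibble::tibble(i = integer(), j = integer(), distance = numeric()))
  x1 <- coords(sub1); x2 <- coords(sub2)
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), `+`) - 2 * x1 %*% t(x2)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  tibble::tibble(i = hit[, 1], j = hit[, 2],
                 distance = sqrt(pmax(d2[hit], 0)))
}

#' Find inter-chain salt bridges
#'
#' One contact per carboxylate-carbon / cationic-nitrogen(-carbon) pair
#' within `cutoff`: Asp CG and Glu CD on the acidic side, Lys NZ (the
#' ammonium nitrogen, the literal criterion) and Arg CZ (the guanidinium
#' carbon, an analogous extension flagged by `arg_extension = TRUE` in the
#' output) on the basic side.
#'
#' @param atoms atom tibble.
#' @param chain_a,chain_b the two chains.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return A contact tibble: `kind`, `atom_a`, `atom_b`, `distance`,
#'   `angle`, `arg_extension`, sorted and symmetric in chain order.
#' @export
find_salt_bridges <- function(atoms, chain_a, chain_b, cutoff = 4.0) {
  acid <- function(ch) {
    s <- select_atoms(atoms, chain = ch, heavy_only = TRUE, drop_het = TRUE)
    s[(s$res_name == "ASP" & s$atom_name == "CG") |
        (s$res_name == "GLU" & s$atom_name == "CD"), ]
  }
  base <- function(ch) {
    s <- select_atoms(atoms, chain = ch, heavy_only = TRUE, drop_het = TRUE)
    s[(s$res_name %in% c("LYS") & s$atom_name == "NZ") |
        (s$res_name == "ARG" & s$atom_name == "CZ"), ]
  }
  one_way <- function(c1, c2) {
    ac <- acid(c1); bs <- base(c2)
    hits <- cross_pairs(ac, bs, cutoff)
    tibble::tibble(kind = rep("salt_bridge", nrow(hits)),
                   atom_a = atom_label(ac, hits$i),
                   atom_b = atom_label(bs, hits$j),
                   distance = hits$distance,
                   angle = NA_real_,
                   arg_extension = bs$res_name[hits$j] == "ARG")
  }
  out <- dplyr::bind_rows(one_way(chain_a, chain_b), one_way(chain_b, chain_a))
  dplyr::arrange(out, .data$atom_a, .data$atom_b)
}

# Donor table: atom name -> antecedent atom name, per residue scope.
hbond_donors <- function() {
  tibble::tribble(
    ~res, ~donor, ~antecedent, ~backbone,
    "*",   "N",   "CA",  TRUE,
    "LYS", "NZ",  "CE",  FALSE,
    "ARG", "NE",  "CD",  FALSE,
    "ARG", "NH1", "CZ",  FALSE,
    "ARG", "NH2", "CZ",  FALSE,
    "ASN", "ND2", "CG",  FALSE,
    "GLN", "NE2", "CD",  FALSE,
    "HIS", "ND1", "CG",  FALSE,
    "HIS", "NE2", "CE1", FALSE,
    "SER", "OG",  "CB",  FALSE,
    "THR", "OG1", "CB",  FALSE,
    "TYR", "OH",  "CZ",  FALSE,
    "TRP", "NE1", "CD1", FALSE
  )
}

hbond_acceptors <- function() {
  tibble::tribble(
    ~res, ~acceptor, ~backbone,
    "*",   "O",   TRUE,
    "ASP", "OD1", FALSE,
    "ASP", "OD2", FALSE,
    "GLU", "OE1", FALSE,
    "GLU", "OE2", FALSE,
    "ASN", "OD1", FALSE,
    "GLN", "OE1", FALSE,
    "SER", "OG",  FALSE,
    "THR", "OG1", FALSE,
    "TYR", "OH",  FALSE,
    "HIS", "ND1", FALSE,
    "HIS", "NE2", FALSE
  )
}

#' Find inter-chain hydrogen bonds (heavy-atom geometry)
#'
#' Crystal structures rarely resolve hydrogens, so the criterion is purely
#' heavy-atom: donor-acceptor distance <= `d_cutoff` and
#' antecedent-donor-acceptor angle >= `angle_cutoff`. Backbone-backbone
#' pairs are flagged `kind = "backbone_hbond"`.
#'
#' @param atoms atom tibble.
#' @param chain_a,chain_b the two chains.
#' @param d_cutoff donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cutoff minimum antecedent-donor-acceptor angle, degrees
#'   (default 90).
#' @return A contact tibble (see [find_salt_bridges()]).
#' @export
find_hbonds <- function(atoms, chain_a, chain_b, d_cutoff = 3.5,
                        angle_cutoff = 90) {
  don_tab <- hbond_donors(); acc_tab <- hbond_acceptors()
  pick <- function(ch, tab, col) {
    s <- select_atoms(atoms, chain = ch, heavy_only = TRUE, drop_het = TRUE)
    any_res <- tab$res == "*"
    sel <- (s$atom_name %in% tab[[col]][any_res]) |
      (paste(s$res_name, s$atom_name) %in% paste(tab$res[!any_res], tab[[col]][!any_res]))
    s[sel, ]
  }
  one_way <- function(c1, c2) {
    don <- pick(c1, don_tab, "donor")
    acc <- pick(c2, acc_tab, "acceptor")
    hits <- cross_pairs(don, acc, d_cutoff)
    if (nrow(hits) == 0) return(tibble::tibble())
    full1 <- select_atoms(atoms, chain = c1, heavy_only = TRUE, drop_het = TRUE)
    rows <- list()
    for (k in seq_len(nrow(hits))) {
      i <- hits$i[k]; j <- hits$j[k]
      is_bb_don <- don$atom_name[i] == "N"
      ante_name <- if (is_bb_don) "CA" else
        don_tab$antecedent[match(paste(don$res_name[i], don$atom_name[i]),
                                 paste(don_tab$res, don_tab$donor))]
      ante <- full1[full1$res_seq == don$res_seq[i] & full1$ins == don$ins[i] &
                      full1$atom_name == ante_name, ]
      if (nrow(ante) == 0) next
      v1 <- c(ante$x[1], ante$y[1], ante$z[1]) -
        c(don$x[i], don$y[i], don$z[i])
      v2 <- c(acc$x[j], acc$y[j], acc$z[j]) - c(don$x[i], don$y[i], don$z[i])
      ang <- acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * 180 / pi
      if (ang < angle_cutoff) next
      is_bb <- is_bb_don && acc$atom_name[j] == "O"
      rows[[length(rows) + 1]] <- tibble::tibble(
        kind = if (is_bb) "backbone_hbond" else "hbond",
        atom_a = atom_label(don, i), atom_b = atom_label(acc, j),
        distance = hits$distance[k], angle = ang, arg_extension = FALSE)
    }
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(one_way(chain_a, chain_b), one_way(chain_b, chain_a))
  if (nrow(out) == 0) return(tibble::tibble(
    kind = character(), atom_a = character(), atom_b = character(),
    distance = numeric(), angle = numeric(), arg_extension = logical()))
  dplyr::arrange(out, .data$atom_a, .data$atom_b)
}

ring_atoms <- function() {
  list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
       TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
       TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
       HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
       ARG = c("NE", "CZ", "NH1", "NH2"))
}

#' Find inter-chain ring stacking contacts
#'
#' Aromatic rings (Phe/Tyr/Trp/His) and the Arg guanidinium plane are
#' reduced to centroid + fitted plane normal; pairs with centroid distance
#' <= `centroid_cutoff` are reported with the interplanar angle.
#'
#' @param atoms atom tibble.
#' @param chain_a,chain_b the two chains.
#' @param centroid_cutoff centroid distance cutoff, Angstrom (default 6.0).
#' @return A contact tibble with `angle` = interplanar angle (0-90 deg).
#' @export
find_stacking <- function(atoms, chain_a, chain_b, centroid_cutoff = 6.0) {
  rings_of <- function(ch) {
    defs <- ring_atoms()
    s <- select_atoms(atoms, chain = ch, heavy_only = TRUE, drop_het = TRUE)
    s <- s[s$res_name %in% names(defs), ]
    out <- list()
    for (key in unique(paste(s$res_seq, s$ins))) {
      r <- s[paste(s$res_seq, s$ins) == key, ]
      need <- defs[[r$res_name[1]]]
      ra <- r[r$atom_name %in% need, ]
      if (nrow(ra) < length(need)) next   # incomplete sidechain
      xyz <- coords(ra)
      ctr <- colMeans(xyz)
      normal <- svd(sweep(xyz, 2, ctr))$v[, 3]
      out[[length(out) + 1]] <- list(
        label = paste0(ch, ":", r$res_name[1], r$res_seq[1]),
        centroid = ctr, normal = normal)
    }
    out
  }
  ra <- rings_of(chain_a); rb <- rings_of(chain_b)
  rows <- list()
  for (p in ra) for (q in rb) {
    d <- vnorm(p$centroid - q$centroid)
    if (d > centroid_cutoff) next
    cosang <- abs(sum(p$normal * q$normal))
    rows[[length(rows) + 1]] <- tibble::tibble(
      kind = "stacking", atom_a = p$label, atom_b = q$label, distance = d,
      angle = acos(max(-1, min(1, cosang))) * 180 / pi, arg_extension = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(tibble::tibble(
    kind = character(), atom_a = character(), atom_b = character(),
    distance = numeric(), angle = numeric(), arg_extension = logical()))
  dplyr::arrange(out, .data$atom_a, .data$atom_b)
}
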