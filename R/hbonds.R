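# Static backbone hydrogen-bond detection on PDB structures.

#' Parse a PDB structure into an atom table
#'
#' Reads a PDB file (via bio3d), selects one model (first by default, for
#' NMR ensembles), and collapses alternate locations to the
#' highest-occupancy conformer per atom. Hydrogens are retained when
#' present.
#'
#' @param path PDB file.
#' @param model model number to extract (default 1).
#' @return a `pdb_atoms` data frame: `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `x`, `y`, `z`, `occ`, `model`.
#' @export
parse_structure <- function(path, model = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models) || n_models < 1) stop("empty structure")
  if (model < 1 || model > n_models)
    stop(sprintf("model %d not present (%d models)", model, n_models))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  sel <- which(pdb$atom$type == "ATOM")
  out <- data.frame(chain = at$chain, resno = at$resno,
                    insert = ifelse(is.na(at$insert), "", at$insert),
                    resid = at$resid, elety = at$elety,
                    x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3],
                    occ = ifelse(is.na(at$o), 1, at$o),
                    alt = ifelse(is.na(at$alt), "", at$alt),
                    model = model)
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z)))
    stop("malformed coordinates")
  # highest-occupancy altloc per (chain, residue, atom name)
  key <- paste(out$chain, out$resno, out$insert, out$elety)
  ord <- order(key, -out$occ, out$alt)
  out <- out[ord, ][!duplicated(key[ord]), ]
  out <- out[order(out$chain, out$resno, out$insert), ]
  rownames(out) <- NULL
  class(out) <- c("pdb_atoms", "data.frame")
  out
}

# residue-level table of the backbone atoms needed for H-bond geometry
.backbone_table <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  res <- atoms[!duplicated(key), c("chain", "resno", "insert", "resid")]
  res$key <- unique(key)
  pick <- function(name) {
    m <- atoms[atoms$elety %in% name, ]
    idx <- match(res$key, paste(m$chain, m$resno, m$insert))
    cbind(m$x[idx], m$y[idx], m$z[idx])
  }
  res$N <- pick("N")
  res$H <- pick(c("H", "HN"))
  res$O <- pick("O")
  rownames(res) <- NULL
  res
}

#' Detect backbone hydrogen bonds by geometric criteria
#'
#' Candidate bonds are backbone amide nitrogens (donors; proline is
#' excluded) paired with backbone carbonyl oxygens (acceptors) of residues
#' at least `min_sep` apart in sequence (different chains always qualify).
#' A pair is accepted when the donor-to-acceptor heavy-atom distance
#' N...O is at most `d_cut` and, when the amide hydrogen is present in
#' the model, the D-H...A deviation from linearity is at most
#' `angle_cut` degrees (i.e. the angle at the hydrogen is at least
#' 180 - `angle_cut`). When no hydrogen exists the bond is accepted on
#' distance alone and flagged `distance_only`.
#'
#' @param atoms a `pdb_atoms` table from [parse_structure()].
#' @param d_cut donor-acceptor distance cutoff, Angstrom (default 4).
#' @param angle_cut deviation-from-linear cutoff, degrees (default 30).
#' @param min_sep minimum intra-chain residue separation (default 2).
#' @return an `hbond_table` data frame: `donor_chain`, `donor_resno`,
#'   `acceptor_chain`, `acceptor_resno`, `dist`, `angle_dev`,
#'   `distance_only`.
#' @export
find_backbone_hbonds <- function(atoms, d_cut = 4.0, angle_cut = 30,
                                 min_sep = 2) {
  bb <- .backbone_table(atoms)
  don <- which(!is.na(bb$N[, 1]) & bb$resid != "PRO")
  acc <- which(!is.na(bb$O[, 1]))
  if (length(don) == 0 || length(acc) == 0) stop("no backbone N/O atoms")
  rows <- list()
  for (i in don) {
    Ni <- bb$N[i, ]
    for (j in acc) {
      if (i == j) next
      same_chain <- bb$chain[i] == bb$chain[j]
      if (same_chain && abs(bb$resno[i] - bb$resno[j]) < min_sep) next
      Oj <- bb$O[j, ]
      d <- sqrt(sum((Ni - Oj)^2))
      if (d > d_cut) next
      has_h <- !is.na(bb$H[i, 1])
      dev <- NA_real_
      if (has_h) {
        Hi <- bb$H[i, ]
        v1 <- Ni - Hi
        v2 <- Oj - Hi
        ang <- acos(pmin(pmax(sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2))),
                              -1), 1)) * 180 / pi
        dev <- 180 - ang
        if (dev > angle_cut) next
      }
      rows[[length(rows) + 1]] <- data.frame(
        donor_chain = bb$chain[i], donor_resno = bb$resno[i],
        acceptor_chain = bb$chain[j], acceptor_resno = bb$resno[j],
        dist = d, angle_dev = dev, distance_only = !has_h)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_chain = character(0), donor_resno = integer(0),
               acceptor_chain = character(0), acceptor_resno = integer(0),
               dist = numeric(0), angle_dev = numeric(0),
               distance_only = logical(0))
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' Count hydrogen bonds connecting two residue ranges
#'
#' Counts bonds with one partner in each of two disjoint residue sets
#' (either direction), e.g. the mechanical-clamp bonds between the
#' terminal beta-strands of an immunoglobulin-like domain.
#'
#' @param hbonds an `hbond_table`.
#' @param rangeA,rangeB residue-number vectors (disjoint).
#' @return integer count.
#' @export
interstrand_count <- function(hbonds, rangeA, rangeB) {
  if (length(intersect(rangeA, rangeB)) > 0)
    stop("residue ranges must be disjoint")
  ab <- hbonds$donor_resno %in% rangeA & hbonds$acceptor_resno %in% rangeB
  ba <- hbonds$donor_resno %in% rangeB & hbonds$acceptor_resno %in% rangeA
  sum(ab | ba)
}

#' Beta-strand segments from the backbone hydrogen-bond pattern
#'
#' Assigns strand residues from ladder motifs in the long-range backbone
#' hydrogen bonds: a residue is strand-like when it partners another
#' residue at sequence separation >= `min_sep` and a close sequence
#' neighbour (within 2 residues) partners a close neighbour of the same
#' partner — two rungs of a beta-ladder. Runs of strand-like residues
#' (single-residue gaps tolerated) become strands, labelled A, B, ... in
#' sequence order.
#'
#' @param hbonds an `hbond_table` (single chain assumed for labelling).
#' @param min_sep minimum sequence separation for ladder bonds
#'   (default 3).
#' @return data frame `strand`, `start`, `end` (residue numbers).
#' @export
find_strands <- function(hbonds, min_sep = 3) {
  prs <- unique(data.frame(
    i = pmin(hbonds$donor_resno, hbonds$acceptor_resno),
    j = pmax(hbonds$donor_resno, hbonds$acceptor_resno)))
  prs <- prs[prs$j - prs$i >= min_sep, , drop = FALSE]
  marked <- integer(0)
  if (nrow(prs) > 1) {
    for (a in seq_len(nrow(prs))) {
      near <- abs(prs$i - prs$i[a]) <= 2 & abs(prs$j - prs$j[a]) <= 2
      near[a] <- FALSE
      if (any(near & (prs$i != prs$i[a] | prs$j != prs$j[a])))
        marked <- c(marked, prs$i[a], prs$j[a])
    }
  }
  marked <- sort(unique(marked))
  if (length(marked) == 0)
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0)))
  gaps <- which(diff(marked) > 2)
  starts <- c(1, gaps + 1)
  ends <- c(gaps, length(marked))
  data.frame(strand = LETTERS[seq_along(starts)],
             start = marked[starts], end = marked[ends])
}

#' Construct an ideal antiparallel two-strand beta-sheet (synthetic)
#'
#' Builds backbone coordinates (N, H, CA, C, O per residue) for two
#' antiparallel strands at idealized hydrogen-bonding geometry: residue
#' pairs alternate between doubly hydrogen-bonded rungs (N-H...O=C in
#' both directions, N...O around 2.9 Angstrom, perfectly linear) and
#' non-bonded rungs whose amide and carbonyl groups point away from the
#' partner strand, the alternation characteristic of antiparallel
#' ladders. This is a synthetic geometric fixture for exercising bond
#' detection and strand assignment, not a model of any real protein.
#'
#' @param n_res residues per strand; rungs 1, 3, 5, ... are bonded, so
#'   `n_res = 4` yields 4 ladder bonds and `n_res = 6` yields 6.
#' @param separation extra strand separation in Angstrom added along the
#'   inter-strand axis (pulling the strands apart breaks the bonds).
#' @param chain chain identifier.
#' @return a `pdb_atoms` table; strand 1 is residues `1..n_res`, strand 2
#'   occupies residues `n_res + 3 .. 2 n_res + 2` running antiparallel.
#' @export
synthetic_beta_sheet <- function(n_res = 4, separation = 0, chain = "A") {
  rows <- list()
  add <- function(resno, elety, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resid = "ALA",
      elety = elety, x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
      alt = "", model = 1)
  }
  for (p in seq_len(n_res)) {
    s <- 3.5 * (p - 1)
    bonded <- p %% 2 == 1
    # strand 1 residue p
    add(p, "N", c(s, 0, 0))
    add(p, "H", c(s, if (bonded) 1.0 else -1.0, 0))
    add(p, "CA", c(s + 1.0, -0.8, 0.4))
    add(p, "C", c(s + 2.0, 0, 0))
    add(p, "O", c(s + 2.0, if (bonded) 1.23 else -1.23, 0))
    # strand 2 partner residue (antiparallel)
    q <- 2L * n_res + 3L - p
    y0 <- 4.13 + separation
    add(q, "N", c(s + 2.0, y0, 0))
    add(q, "H", c(s + 2.0, if (bonded) y0 - 1.0 else y0 + 1.0, 0))
    add(q, "CA", c(s + 1.0, y0 + 0.8, -0.4))
    add(q, "C", c(s, y0, 0))
    add(q, "O", c(s, if (bonded) y0 - 1.2 else y0 + 1.23, 0))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$resno), ]
  rownames(out) <- NULL
  class(out) <- c("pdb_atoms", "data.frame")
  out
}

#' Write an atom table as a PDB file
#'
#' Minimal writer for fixtures and exports (delegates to bio3d).
#'
#' @param atoms a `pdb_atoms` table.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_structure <- function(atoms, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, resid = atoms$resid,
                   elety = atoms$elety, chain = atoms$chain,
                   o = atoms$occ)
  invisible(path)
}
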