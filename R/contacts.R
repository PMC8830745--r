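# Protein-lipid and protein-protein contacts: any-atom minimum-distance
# residue contacts under the periodic minimum-image convention, with an exact
# cell-list acceleration; persistence (total, not necessarily consecutive,
# time in contact); stable-residue filtering (> 500 ns, strict); per-type
# frequency tallies; and variant-annotation intersection.

# residue-level atom grouping for a contact search
contact_groups <- function(system, kind = c("lipid", "protein")) {
  kind <- match.arg(kind)
  a <- system$atoms
  if (kind == "lipid") which(is_lipid_class(a$class)) else which(a$class == "protein")
}

# exact brute-force residue contact pairs between atom sets
contacts_brute <- function(xyz, a, idx_a, idx_b, cutoff, box) {
  d2 <- pair_dist2(xyz[idx_a, , drop = FALSE], xyz[idx_b, , drop = FALSE], box)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(character(0))
  unique(paste(a$chain[idx_a][hit[, 1]], a$resid[idx_a][hit[, 1]],
               a$chain[idx_b][hit[, 2]], a$resid[idx_b][hit[, 2]], sep = "\r"))
}

# cell-list accelerated contact pairs; exactly equivalent to brute force
contacts_grid <- function(xyz, a, idx_a, idx_b, cutoff, box) {
  nc <- pmax(1L, floor(box / cutoff))
  if (any(nc < 3)) return(contacts_brute(xyz, a, idx_a, idx_b, cutoff, box))
  cw <- box / nc
  cell_of <- function(idx) {
    ci <- floor(wrap_pbc(xyz[idx, 1], box[1]) / cw[1]) %% nc[1]
    cj <- floor(wrap_pbc(xyz[idx, 2], box[2]) / cw[2]) %% nc[2]
    ck <- floor(wrap_pbc(xyz[idx, 3], box[3]) / cw[3]) %% nc[3]
    cbind(ci, cj, ck)
  }
  cb <- cell_of(idx_b)
  lin_b <- (cb[, 3] * nc[2] + cb[, 2]) * nc[1] + cb[, 1] + 1
  buckets <- split(seq_along(idx_b), lin_b)
  ca <- cell_of(idx_a)
  out <- character(0)
  # group A atoms by cell, then scan the 27 neighbouring cells
  lin_a <- (ca[, 3] * nc[2] + ca[, 2]) * nc[1] + ca[, 1] + 1
  for (cell in unique(lin_a)) {
    ai <- which(lin_a == cell)
    c0 <- ca[ai[1], ]
    nb_idx <- integer(0)
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      ci <- (c0[1] + di) %% nc[1]
      cj <- (c0[2] + dj) %% nc[2]
      ck <- (c0[3] + dk) %% nc[3]
      key <- as.character((ck * nc[2] + cj) * nc[1] + ci + 1)
      nb_idx <- c(nb_idx, buckets[[key]])
    }
    nb_idx <- unique(nb_idx)
    if (!length(nb_idx)) next
    sub_a <- idx_a[ai]
    sub_b <- idx_b[nb_idx]
    d2 <- pair_dist2(xyz[sub_a, , drop = FALSE], xyz[sub_b, , drop = FALSE], box)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit))
      out <- c(out, paste(a$chain[sub_a][hit[, 1]], a$resid[sub_a][hit[, 1]],
                          a$chain[sub_b][hit[, 2]], a$resid[sub_b][hit[, 2]],
                          sep = "\r"))
  }
  unique(out)
}

#' Residue contact pairs in one frame
#'
#' A protein residue and a partner residue are in contact when the minimum
#' Euclidean distance over their atom pairs (periodic minimum image) is at
#' most the cutoff.
#'
#' @param system a \code{\link{molecular_system}}.
#' @param xyz frame coordinates (default the system's own).
#' @param cutoff contact cutoff in Angstrom (default 5, i.e. the 0.5 nm
#'   shell).
#' @param partner \code{"lipid"} or \code{"protein"}.
#' @param method \code{"grid"} (cell list; exact) or \code{"brute"}.
#' @return data.frame with \code{protein_resid}, \code{partner_chain},
#'   \code{partner_resid}, \code{partner_resname}.
#' @export
frame_contacts <- function(system, xyz = NULL, cutoff = 5,
                           partner = c("lipid", "protein"),
                           method = c("grid", "brute")) {
  partner <- match.arg(partner); method <- match.arg(method)
  if (cutoff <= 0) stopf("cutoff must be > 0")
  if (is.null(xyz)) xyz <- coords(system)
  a <- system$atoms
  idx_a <- contact_groups(system, "protein")
  idx_b <- contact_groups(system, partner)
  if (!length(idx_a) || !length(idx_b))
    return(data.frame(protein_resid = integer(0), partner_chain = character(0),
                      partner_resid = integer(0), partner_resname = character(0)))
  keys <- if (method == "grid")
    contacts_grid(xyz, a, idx_a, idx_b, cutoff, system$box)
  else contacts_brute(xyz, a, idx_a, idx_b, cutoff, system$box)
  if (!length(keys))
    return(data.frame(protein_resid = integer(0), partner_chain = character(0),
                      partner_resid = integer(0), partner_resname = character(0)))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(
    protein_resid = as.integer(parts[, 2]),
    partner_chain = parts[, 3],
    partner_resid = as.integer(parts[, 4]),
    stringsAsFactors = FALSE
  )
  if (partner == "protein")
    out <- out[out$partner_resid != out$protein_resid, , drop = FALSE]
  rkey <- paste(system$residues$chain, system$residues$resid)
  out$partner_resname <-
    system$residues$resname[match(paste(out$partner_chain, out$partner_resid), rkey)]
  out <- out[order(out$protein_resid, out$partner_chain, out$partner_resid), ]
  rownames(out) <- NULL
  out
}

#' Contact persistence over a trajectory
#'
#' Accumulates, per (protein residue, partner residue) pair, the number of
#' frames in contact over the whole stream (not necessarily consecutive) and
#' the corresponding time \code{frames * dt}.
#'
#' @param stream a \code{\link{frame_stream}}.
#' @param system the parent system.
#' @param cutoff contact cutoff (Angstrom, default 5).
#' @param partner \code{"lipid"} or \code{"protein"}.
#' @param method \code{"grid"} or \code{"brute"}.
#' @return a \code{contact_table} data.frame: \code{protein_resid},
#'   \code{partner_chain}, \code{partner_resid}, \code{partner_resname},
#'   \code{partner_kind}, \code{frames_in_contact}, \code{contact_time_ns};
#'   attributes \code{n_frames} and \code{dt_ps}.
#' @export
persistence <- function(stream, system, cutoff = 5,
                        partner = c("lipid", "protein"),
                        method = c("grid", "brute")) {
  partner <- match.arg(partner); method <- match.arg(method)
  counts <- new.env(parent = emptyenv())
  for (k in seq_len(stream$n_frames)) {
    fc <- frame_contacts(system, frame_coords(stream, k), cutoff, partner, method)
    if (!nrow(fc)) next
    keys <- paste(fc$protein_resid, fc$partner_chain, fc$partner_resid, sep = "\r")
    for (key in keys) counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  keys <- ls(counts)
  if (!length(keys)) {
    out <- data.frame(protein_resid = integer(0), partner_chain = character(0),
                      partner_resid = integer(0), partner_resname = character(0),
                      partner_kind = character(0), frames_in_contact = integer(0),
                      contact_time_ns = numeric(0))
  } else {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    nfr <- vapply(keys, function(k) counts[[k]], integer(1))
    rkey <- paste(system$residues$chain, system$residues$resid)
    ridx <- match(paste(parts[, 2], parts[, 3]), rkey)
    out <- data.frame(
      protein_resid = as.integer(parts[, 1]),
      partner_chain = parts[, 2],
      partner_resid = as.integer(parts[, 3]),
      partner_resname = system$residues$resname[ridx],
      partner_kind = ifelse(is_lipid_class(system$residues$class[ridx]),
                            system$residues$class[ridx], "protein"),
      frames_in_contact = unname(nfr),
      contact_time_ns = unname(nfr) * stream$dt / 1000,
      stringsAsFactors = FALSE
    )
    out <- out[order(out$protein_resid, out$partner_chain, out$partner_resid), ]
    rownames(out) <- NULL
  }
  attr(out, "n_frames") <- stream$n_frames
  attr(out, "dt_ps") <- stream$dt
  class(out) <- c("contact_table", class(out))
  out
}

#' Protein residues with persistent lipid contacts
#'
#' A residue qualifies when it has at least one lipid partner with total
#' contact time strictly greater than \code{min_time_ns} ("more than
#' 500 ns": a partner at exactly 500.0 ns does not count).
#'
#' @param table a \code{contact_table} from \code{\link{persistence}}.
#' @param min_time_ns persistence threshold in ns (default 500).
#' @return data.frame with \code{protein_resid}, \code{n_partners} (stable
#'   lipid partners) and one count column per lipid type present.
#' @export
stable_residues <- function(table, min_time_ns = 500) {
  t2 <- table[startsWith(table$partner_kind, "lipid:") &
              table$contact_time_ns > min_time_ns, , drop = FALSE]
  if (!nrow(t2))
    return(data.frame(protein_resid = integer(0), n_partners = integer(0)))
  types <- sort(unique(t2$partner_resname))
  res <- sort(unique(t2$protein_resid))
  out <- data.frame(protein_resid = res)
  out$n_partners <- vapply(res, function(r) sum(t2$protein_resid == r), integer(1))
  for (ty in types)
    out[[ty]] <- vapply(res, function(r)
      sum(t2$protein_resid == r & t2$partner_resname == ty), integer(1))
  out
}

#' Frequency of lipid types in the contact shell
#'
#' Two tallies per lipid type: \code{partnerships} (distinct protein
#' residue-lipid pairs) and \code{frame_events} (their summed
#' frames-in-contact), ordered by descending partnerships, ties alphabetical.
#'
#' @param table a \code{contact_table}.
#' @param min_time_ns drop pairs at or below this persistence (default 0
#'   keeps all).
#' @return data.frame with \code{lipid_type}, \code{partnerships},
#'   \code{frame_events}.
#' @export
lipid_type_frequency <- function(table, min_time_ns = 0) {
  t2 <- table[startsWith(table$partner_kind, "lipid:") &
              table$contact_time_ns > min_time_ns, , drop = FALSE]
  if (!nrow(t2))
    return(data.frame(lipid_type = character(0), partnerships = integer(0),
                      frame_events = integer(0)))
  types <- unique(t2$partner_resname)
  out <- data.frame(
    lipid_type = types,
    partnerships = vapply(types, function(ty) sum(t2$partner_resname == ty), integer(1)),
    frame_events = vapply(types, function(ty)
      sum(t2$frames_in_contact[t2$partner_resname == ty]), numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$partnerships, out$lipid_type), ]
  rownames(out) <- NULL
  out
}

#' Stable protein-protein contacts of selected residues
#'
#' The same persistence machinery restricted to protein partners, excluding
#' trivial sequence neighbours within +/- \code{exclude_window} residues on
#' the same chain.
#'
#' @param stream a \code{\link{frame_stream}}.
#' @param system the parent system.
#' @param residue_subset protein residue ids to report (NULL = all).
#' @param cutoff contact cutoff (Angstrom).
#' @param min_time_ns persistence threshold (strict >; default 500).
#' @param exclude_window sequence-neighbour exclusion half-width (default 2).
#' @return data.frame with \code{protein_resid}, \code{n_partners},
#'   \code{total_time_ns}.
#' @export
protein_protein_contacts <- function(stream, system, residue_subset = NULL,
                                     cutoff = 5, min_time_ns = 500,
                                     exclude_window = 2) {
  tab <- persistence(stream, system, cutoff, partner = "protein")
  tab <- tab[abs(tab$partner_resid - tab$protein_resid) > exclude_window, , drop = FALSE]
  tab <- tab[tab$contact_time_ns > min_time_ns, , drop = FALSE]
  res <- residue_subset %||% sort(unique(system$residues$resid[
    system$residues$class == "protein"]))
  data.frame(
    protein_resid = res,
    n_partners = vapply(res, function(r) sum(tab$protein_resid == r), integer(1)),
    total_time_ns = vapply(res, function(r)
      sum(tab$contact_time_ns[tab$protein_resid == r]), numeric(1))
  )
}

#' Read a residue annotation table
#'
#' CSV with columns \code{residue_id}, \code{variant_label} and optionally
#' \code{source} / \code{pathogenicity}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  an <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("residue_id", "variant_label") %in% names(an)))
    stopf("annotation needs residue_id and variant_label columns")
  an
}

#' Intersect stable residues with an annotation table
#'
#' Keeps annotation rows whose residue id is in the stable list (deletion and
#' frameshift labels match by position alone, like any other). Duplicate
#' (residue, variant) rows are collapsed with their sources concatenated.
#'
#' @param stable data.frame from \code{\link{stable_residues}} (or an integer
#'   vector of residue ids).
#' @param annotation data.frame from \code{\link{read_annotation}}.
#' @return the intersected annotation rows, ordered by residue id.
#' @export
annotate_variants <- function(stable, annotation) {
  ids <- if (is.data.frame(stable)) stable$protein_resid else as.integer(stable)
  hit <- annotation[annotation$residue_id %in% ids, , drop = FALSE]
  if (!nrow(hit)) return(hit)
  key <- paste(hit$residue_id, hit$variant_label)
  if (anyDuplicated(key)) {
    src <- if ("source" %in% names(hit)) hit$source else rep("", nrow(hit))
    agg <- tapply(src, key, function(s) paste(unique(s), collapse = ";"))
    hit <- hit[!duplicated(key), , drop = FALSE]
    hit$source <- as.vector(agg[paste(hit$residue_id, hit$variant_label)])
  }
  hit <- hit[order(hit$residue_id), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}
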