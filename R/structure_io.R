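# Reading RNA 3D structures into an ordered residue model.
#
# The in-memory model is an "rna_structure": a residue table plus one
# coordinate matrix per residue.  All downstream indices (pairs, helices,
# writers) are 1-based positions in this selected residue set; author
# residue numbers are carried along for reporting only.

.std_bases <- c("A", "C", "G", "U")

.parent_base <- function(comp) {
  comp <- toupper(comp)
  out <- ifelse(comp %in% .std_bases, comp,
                unname(.modified_parent[comp]))
  out
}

new_rna_structure <- function(residues, atoms) {
  stopifnot(nrow(residues) == length(atoms))
  residues$global_index <- seq_len(nrow(residues))
  structure(list(residues = residues, atoms = atoms),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  ch <- table(x$residues$chain_id)
  cat(sprintf("rna_structure: %d residues in %d chain(s)\n",
              nrow(x$residues), length(ch)))
  for (nm in names(ch)) cat(sprintf("  chain %s: %d nt\n", nm, ch[[nm]]))
  invisible(x)
}

#' Number of residues in an RNA structure
#' @param x an `rna_structure`.
#' @return integer residue count.
#' @export
n_residues <- function(x) nrow(x$residues)

# --- mmCIF atom_site parsing ------------------------------------------------
# Header-mapped parser for the atom_site loop: column order is taken from
# the _atom_site.* item names, so files with any column subset or order
# are read correctly.

.parse_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0)
    stop("parse error in '", path, "': no _atom_site loop found")
  if (any(diff(hdr_idx) != 1))
    stop("parse error in '", path, "': _atom_site items are not contiguous ",
         "(near line ", hdr_idx[which(diff(hdr_idx) != 1)[1] + 1], ")")
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  rows <- character(0)
  for (k in body_start:length(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" ) next
    if (startsWith(ln, "#") || startsWith(ln, "_") || startsWith(ln, "loop_") ||
        startsWith(ln, "data_")) break
    rows <- c(rows, ln)
  }
  if (length(rows) == 0)
    stop("parse error in '", path, "': empty _atom_site loop")
  mat <- do.call(rbind, strsplit(rows, "[ \t]+"))
  if (ncol(mat) != length(cols))
    stop("parse error in '", path, "': _atom_site row with ", ncol(mat),
         " fields, expected ", length(cols))
  colnames(mat) <- cols
  need <- c("label_atom_id", "label_comp_id", "Cartn_x", "Cartn_y", "Cartn_z")
  miss <- setdiff(need, cols)
  if (length(miss) > 0)
    stop("parse error in '", path, "': missing atom_site item(s) ",
         paste(miss, collapse = ", "))
  get <- function(nm, alt = NA) {
    if (nm %in% cols) mat[, nm] else rep(alt, nrow(mat))
  }
  # strip mmCIF quoting on atom names (e.g. "C1'")
  atom <- gsub('^"|"$', "", get("label_atom_id"))
  data.frame(
    type   = get("group_PDB", "ATOM"),
    elety  = atom,
    resid  = toupper(get("label_comp_id")),
    chain  = get("auth_asym_id", alt = NA),
    chain_label = get("label_asym_id", alt = NA),
    resno  = suppressWarnings(as.integer(get("auth_seq_id", alt = NA))),
    seqno  = suppressWarnings(as.integer(get("label_seq_id", alt = NA))),
    alt    = get("label_alt_id", "."),
    x      = as.numeric(get("Cartn_x")),
    y      = as.numeric(get("Cartn_y")),
    z      = as.numeric(get("Cartn_z")),
    o      = suppressWarnings(as.numeric(get("occupancy", "1"))),
    model  = suppressWarnings(as.integer(get("pdbx_PDB_model_num", "1"))),
    stringsAsFactors = FALSE)
}

.parse_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nmod <- max(1L, length(pdb$xyz) %/% (3L * nrow(at)))
  out <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    out[[m]] <- data.frame(
      type = at$type, elety = at$elety, resid = toupper(at$resid),
      chain = at$chain, chain_label = at$chain, resno = at$resno,
      seqno = NA_integer_,
      alt = ifelse(is.na(at$alt), ".", at$alt),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      o = ifelse(is.na(at$o), 1, at$o), model = m,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Keep the highest-occupancy alternate conformer per atom; ties go to the
# first conformer in file order.
.resolve_altloc <- function(at) {
  at$..row <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "\r")
  keep <- unlist(lapply(split(at$..row, key), function(rows) {
    if (length(rows) == 1) return(rows)
    occ <- at$o[rows]
    rows[which.max(occ)]   # which.max takes the first maximum
  }), use.names = FALSE)
  at <- at[sort(keep), ]
  at$..row <- NULL
  at
}

#' Read an RNA 3D structure from mmCIF or PDB
#'
#' Parses the file, keeps one model, optionally restricts to the given
#' (author) chain ids, and retains only ribonucleotide residues:
#' standard A/C/G/U plus recognized modified nucleotides, which are
#' mapped to their parent base.  Protein, water, ions, ligands and
#' unrecognized residues are dropped (unknown nucleotide-like residues
#' with a warning).  Residues are returned in file order with a 1-based
#' `global_index` that all downstream coordinates use.
#'
#' @param path mmCIF (`.cif`) or PDB file.  Format is chosen by
#'   extension; anything not ending in `.pdb`/`.ent` is parsed as mmCIF.
#' @param model_index model number to keep (default 1).
#' @param chains optional character vector of author chain ids.
#' @return An `rna_structure`: `$residues` is a data frame with columns
#'   `global_index`, `chain_id`, `seq_index` (1-based within chain),
#'   `auth_number`, `base_code` (as in the file), `base` (parent
#'   A/C/G/U), `complete_base`; `$atoms` is a list of per-residue
#'   coordinate matrices (rows named by atom).
#' @export
#' @examples
#' fx <- make_ideal_duplex("GCGC", dir = tempdir())
#' read_structure(fx$path)
read_structure <- function(path, model_index = 1L, chains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_pdb <- grepl("\\.(pdb|ent)(\\.gz)?$", path, ignore.case = TRUE)
  at <- if (is_pdb) .parse_pdb_atoms(path) else .parse_cif_atoms(path)
  if (!model_index %in% at$model)
    stop("model ", model_index, " not present (models: ",
         paste(sort(unique(at$model)), collapse = ", "), ")")
  at <- at[at$model == model_index, , drop = FALSE]
  if (!is.null(chains)) {
    avail <- unique(at$chain)
    bad <- setdiff(chains, avail)
    if (length(bad) > 0)
      stop("chain(s) not found: ", paste(bad, collapse = ", "),
           " (available: ", paste(avail, collapse = ", "), ")")
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  at <- .resolve_altloc(at)

  parent <- .parent_base(at$resid)
  unknown <- unique(at$resid[is.na(parent) &
                               !at$resid %in% c("HOH", "WAT", "MG", "K", "NA", "CL", "ZN")])
  # silently drop water/ions; warn once for anything else non-RNA that
  # looks residue-like (single letters are likely nucleotide variants)
  unk_warn <- unknown[nchar(unknown) <= 3 & grepl("^[A-Z0-9]+$", unknown) &
                        !unknown %in% c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY",
                                        "HIS","ILE","LEU","LYS","MET","PHE","PRO","SER",
                                        "THR","TRP","TYR","VAL","DA","DC","DG","DT")]
  if (length(unk_warn) > 0)
    warning("excluded unrecognized residue type(s): ",
            paste(unk_warn, collapse = ", "))
  at <- at[!is.na(parent), , drop = FALSE]
  if (nrow(at) == 0)
    stop("no RNA residues after filtering in '", path, "'")
  at$parent <- .parent_base(at$resid)

  # split into residues, preserving file order
  rkey <- paste(at$chain, at$resno, at$resid, sep = "\r")
  first <- !duplicated(rkey)
  ord_keys <- rkey[first]
  res_list <- split(seq_len(nrow(at)), factor(rkey, levels = ord_keys))

  chain_id <- at$chain[first]
  res <- data.frame(
    chain_id = chain_id,
    seq_index = stats::ave(seq_along(chain_id), chain_id, FUN = seq_along),
    auth_number = at$resno[first],
    base_code = at$resid[first],
    base = at$parent[first],
    stringsAsFactors = FALSE)

  atoms <- lapply(res_list, function(rows) {
    m <- as.matrix(at[rows, c("x", "y", "z")])
    rownames(m) <- at$elety[rows]
    m[!duplicated(rownames(m)), , drop = FALSE]
  })
  names(atoms) <- NULL
  if (any(!vapply(atoms, function(m) all(is.finite(m)), logical(1))))
    stop("non-finite atom coordinates in '", path, "'")

  ring_ok <- vapply(seq_len(nrow(res)), function(i) {
    all(.ring_atoms[[res$base[i]]] %in% rownames(atoms[[i]]))
  }, logical(1))
  res$complete_base <- ring_ok

  # keep chains in order of first appearance
  new_rna_structure(res, atoms)
}

#' Write an RNA structure to minimal mmCIF
#'
#' Emits a single-model `atom_site` loop with the standard RCSB column
#' set, sufficient for round-tripping through [read_structure()].
#'
#' @param structure an `rna_structure`.
#' @param path output file.
#' @param title data block name.
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(structure, path, title = "rss3d") {
  res <- structure$residues
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con, sep = "\n")
  w(paste0("data_", gsub("[^A-Za-z0-9_]", "_", title)), "#", "loop_")
  w(paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")))
  id <- 0L
  for (i in seq_len(nrow(res))) {
    m <- structure$atoms[[i]]
    for (a in seq_len(nrow(m))) {
      id <- id + 1L
      nm <- rownames(m)[a]
      qnm <- if (grepl("'", nm)) paste0('"', nm, '"') else nm
      w(sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
                id, substr(nm, 1, 1), qnm, res$base_code[i], res$chain_id[i],
                res$seq_index[i], m[a, 1], m[a, 2], m[a, 3],
                res$auth_number[i], res$base_code[i], res$chain_id[i], qnm))
    }
  }
  w("#")
  invisible(path)
}
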