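#' Parse a batch of SMILES into sanitized molecule handles
#'
#' Molecules are parsed and sanitized with OpenBabel. Multi-fragment inputs
#' (salts, co-crystallised solvents) are reduced to the largest organic
#' fragment, so counterions do not inflate molecular weight or acceptor
#' counts. Hydrogens are made explicit on the kept fragment because the
#' Lipinski donor count is a count of N-H and O-H hydrogens, which requires
#' the hydrogens to be present in the graph.
#'
#' @param records data.frame with columns `smiles` and optionally `id` and
#'   `name`. Missing ids are generated as `mol1`, `mol2`, ... Ids must be
#'   unique and non-empty.
#' @return An object of class `dl_molset` with fields `ids`, `smiles`
#'   (input), `cansmi` (canonical SMILES of the kept fragment), `sdf`
#'   (an H-explicit [ChemmineR::SDFset] aligned with `ids`), `graphs`
#'   (per-molecule atom/bond tables), `dropped_fragments` (number of
#'   fragments discarded per molecule) and `failures` (data.frame of
#'   molecules that could not be parsed, with reasons).
#' @seealso [parse_molecule()] for single molecules,
#'   [compute_descriptors()], [morgan_fingerprint()]
#' @export
parse_molecules <- function(records) {
  records <- as_molecule_records(records)
  frag_tab <- fragment_table(records)
  sdf <- obabel_smiles_to_sdf(frag_tab$frag_smiles, frag_tab$frag_id)
  parsed_ids <- ChemmineR::sdfid(sdf)

  keep_idx <- integer(0)   # index into sdf
  keep_rec <- integer(0)   # index into records
  dropped <- integer(0)
  graphs <- list()
  fail_id <- character(0); fail_reason <- character(0)

  for (i in seq_len(nrow(records))) {
    mine <- which(frag_tab$rec_idx == i)
    hit <- match(frag_tab$frag_id[mine], parsed_ids)
    ok <- mine[!is.na(hit)]
    if (length(ok) == 0L) {
      fail_id <- c(fail_id, records$id[i])
      fail_reason <- c(fail_reason, "SMILES could not be parsed by OpenBabel")
      next
    }
    gs <- lapply(hit[!is.na(hit)], function(j) sdf_graph(sdf[[j]]))
    best <- pick_largest_organic(gs)
    keep_idx <- c(keep_idx, hit[!is.na(hit)][best])
    keep_rec <- c(keep_rec, i)
    dropped <- c(dropped, length(mine) - 1L)
    graphs[[length(graphs) + 1L]] <- gs[[best]]
  }

  if (length(keep_idx) == 0L) {
    stop("no molecule could be parsed; first failure: ",
         if (length(fail_id)) paste0("'", fail_id[1], "'") else "none",
         call. = FALSE)
  }
  kept <- sdf[keep_idx]
  cansmi <- obabel_sdf_to_cansmi(kept)
  structure(list(
    ids = records$id[keep_rec],
    smiles = records$smiles[keep_rec],
    names = records$name[keep_rec],
    cansmi = unname(cansmi),
    sdf = kept,
    graphs = graphs,
    dropped_fragments = stats::setNames(dropped, records$id[keep_rec]),
    failures = data.frame(id = fail_id, reason = fail_reason,
                          stringsAsFactors = FALSE)
  ), class = "dl_molset")
}

#' Parse a single SMILES string
#'
#' @param smiles a non-empty SMILES string.
#' @param id identifier used in error messages and outputs.
#' @return A `dl_mol` object (a one-molecule [parse_molecules()] result).
#' @examples
#' \donttest{
#' mol <- parse_molecule("NCC(=O)O", id = "glycine")
#' compute_descriptors(mol)
#' }
#' @export
parse_molecule <- function(smiles, id = "mol1") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("'smiles' must be a single non-empty string (id '", id, "')",
         call. = FALSE)
  }
  ms <- parse_molecules(data.frame(id = id, smiles = smiles,
                                   stringsAsFactors = FALSE))
  if (nrow(ms$failures) > 0L) {
    stop("could not parse SMILES for molecule '", ms$failures$id[1], "': ",
         ms$failures$reason[1], call. = FALSE)
  }
  structure(list(id = ms$ids[1], smiles = ms$smiles[1], cansmi = ms$cansmi[1],
                 sdf = ms$sdf[1], graph = ms$graphs[[1]],
                 dropped_fragments = unname(ms$dropped_fragments[1])),
            class = "dl_mol")
}

#' @export
print.dl_mol <- function(x, ...) {
  cat("<molecule ", x$id, "> ", x$cansmi, "  (",
      sum(x$graph$atoms != "H"), " heavy atoms)\n", sep = "")
  invisible(x)
}

#' @export
print.dl_molset <- function(x, ...) {
  cat("<molecule set> ", length(x$ids), " parsed, ",
      nrow(x$failures), " failed\n", sep = "")
  invisible(x)
}

#' Number of heavy (non-hydrogen) atoms in a parsed molecule
#' @param mol a `dl_mol` object.
#' @return integer count.
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "dl_mol"))
  sum(mol$graph$atoms != "H")
}

#' Canonical descriptor field names
#'
#' The nine descriptor names every rule criterion and feature matrix uses,
#' in canonical column order.
#'
#' @return character vector.
#' @export
descriptor_keys <- function() {
  c("mw", "logp", "hbd", "hba", "tpsa", "n_rotb", "n_carbon", "n_hetero",
    "n_rings")
}

#' Compute the physicochemical descriptor vector of a molecule
#'
#' The nine descriptors every rule set in this package operates on:
#' molecular weight (Da), Wildman-Crippen logP, hydrogen-bond donor count
#' (number of N-H plus O-H hydrogens), hydrogen-bond acceptor count (number
#' of N plus O atoms), Ertl topological polar surface area (A^2), rotatable
#' bonds (strict: acyclic single bonds between two non-terminal heavy atoms,
#' amide C-N excluded), carbon count, heteroatom count (neither C nor H) and
#' ring count (smallest set of smallest rings).
#'
#' MW, logP and TPSA come from OpenBabel; the counting descriptors are
#' derived from the hydrogen-explicit molecular graph so that donor/acceptor
#' counts follow the Lipinski nOH/nNH and nO/nN definitions rather than
#' pharmacophore perception.
#'
#' @param mol a `dl_mol` from [parse_molecule()].
#' @return named numeric vector with elements
#'   `mw, logp, hbd, hba, tpsa, n_rotb, n_carbon, n_hetero, n_rings`.
#' @export
compute_descriptors <- function(mol) {
  stopifnot(inherits(mol, "dl_mol"))
  props <- obabel_properties(mol$sdf, mol$id)
  counts <- graph_descriptors(mol$graph)
  c(mw = props$mw, logp = props$logp, counts[c("hbd", "hba")],
    tpsa = props$tpsa,
    counts[c("n_rotb", "n_carbon", "n_hetero", "n_rings")])
}

#' Descriptor table for a set of molecules
#'
#' Batch version of [compute_descriptors()]: one row per parsed molecule.
#'
#' @param molset a `dl_molset` from [parse_molecules()].
#' @return data.frame with columns `id`, `smiles` (canonical) and the nine
#'   descriptor columns.
#' @export
descriptor_table <- function(molset) {
  stopifnot(inherits(molset, "dl_molset"))
  props <- obabel_properties(molset$sdf, molset$ids)
  counts <- do.call(rbind, lapply(molset$graphs, graph_descriptors))
  out <- data.frame(id = molset$ids, smiles = molset$cansmi,
                    mw = props$mw, logp = props$logp,
                    hbd = counts[, "hbd"], hba = counts[, "hba"],
                    tpsa = props$tpsa, n_rotb = counts[, "n_rotb"],
                    n_carbon = counts[, "n_carbon"],
                    n_hetero = counts[, "n_hetero"],
                    n_rings = counts[, "n_rings"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Morgan-style circular fingerprint of a molecule
#'
#' Extended-connectivity (circular) fingerprint hashed to a fixed-length
#' binary vector, computed with OpenBabel's ECFP implementation; a
#' neighbourhood `radius` of r corresponds to ECFP(2r). The native 4096-bit
#' vector is folded (bitwise OR) down to `n_bits`.
#'
#' @param mol a `dl_mol`.
#' @param radius neighbourhood radius, an integer in 0..5.
#' @param n_bits fingerprint length, a power of two <= 4096.
#' @return integer 0/1 vector of length `n_bits`, named `fp0001`...
#' @export
morgan_fingerprint <- function(mol, radius = 2L, n_bits = 2048L) {
  stopifnot(inherits(mol, "dl_mol"))
  fingerprint_matrix(structure(list(sdf = mol$sdf, ids = mol$id),
                               class = "dl_molset"),
                     radius = radius, n_bits = n_bits)[1, ]
}

#' Fingerprint matrix for a molecule set
#'
#' @param molset a `dl_molset`.
#' @inheritParams morgan_fingerprint
#' @return integer 0/1 matrix, one row per molecule, `n_bits` columns.
#' @export
fingerprint_matrix <- function(molset, radius = 2L, n_bits = 2048L) {
  check_fp_params(radius, n_bits)
  fp <- ChemmineR::fingerprintOB(molset$sdf, paste0("ECFP", 2L * radius))
  m <- methods::slot(fp, "fpma")
  storage.mode(m) <- "integer"
  if (n_bits > ncol(m)) {
    stop("n_bits (", n_bits, ") exceeds the native fingerprint width (",
         ncol(m), ")", call. = FALSE)
  }
  if (n_bits < ncol(m)) {
    fold <- (seq_len(ncol(m)) - 1L) %% n_bits
    m <- t(rowsum(t(m), group = fold))
    m <- (m > 0L) + 0L
  }
  colnames(m) <- sprintf("fp%04d", seq_len(n_bits))
  rownames(m) <- molset$ids
  m
}

check_fp_params <- function(radius, n_bits) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0 ||
      radius > 5 || radius != as.integer(radius)) {
    stop("'radius' must be an integer in 0..5", call. = FALSE)
  }
  if (!is.numeric(n_bits) || length(n_bits) != 1L || n_bits < 1 ||
      bitwAnd(as.integer(n_bits), as.integer(n_bits) - 1L) != 0L) {
    stop("'n_bits' must be a positive power of two", call. = FALSE)
  }
  invisible(TRUE)
}

## ---- readers / writers -----------------------------------------------------

#' Read molecules from a .smi file
#'
#' One molecule per line, whitespace-separated: `SMILES [id]`. Lines without
#' an id get `mol<line>`.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `smiles`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no molecules in '", path, "'", call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[`, "", 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1L) parts[[i]][2L] else paste0("mol", i)
  }, "")
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Read molecules from a CSV file
#'
#' Requires a `smiles` column; `id` and `name` are optional.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `smiles` and, if present, `name`.
#' @export
read_molecule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) {
    stop("'", path, "' has no 'smiles' column", call. = FALSE)
  }
  as_molecule_records(df)
}

#' Write a descriptor table to CSV
#'
#' @param table a data.frame as returned by [descriptor_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- internals -------------------------------------------------------------

as_molecule_records <- function(records) {
  if (is.character(records)) {
    records <- data.frame(smiles = records, stringsAsFactors = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(records)) {
    stop("molecule records need a 'smiles' column", call. = FALSE)
  }
  if (nrow(records) == 0L) stop("empty molecule list", call. = FALSE)
  if (!"id" %in% names(records)) {
    records$id <- paste0("mol", seq_len(nrow(records)))
  }
  if (!"name" %in% names(records)) records$name <- NA_character_
  records$id <- as.character(records$id)
  records$smiles <- as.character(records$smiles)
  bad <- is.na(records$id) | !nzchar(records$id)
  if (any(bad)) stop("empty molecule id at row ", which(bad)[1], call. = FALSE)
  if (anyDuplicated(records$id)) {
    stop("duplicate molecule id: '",
         records$id[duplicated(records$id)][1], "'", call. = FALSE)
  }
  bad <- is.na(records$smiles) | !nzchar(trimws(records$smiles))
  if (any(bad)) {
    stop("empty SMILES for molecule '", records$id[which(bad)[1]], "'",
         call. = FALSE)
  }
  records[c("id", "smiles", "name")]
}

# one row per fragment candidate; "." is the SMILES fragment separator
fragment_table <- function(records) {
  frags <- strsplit(records$smiles, ".", fixed = TRUE)
  n <- lengths(frags)
  data.frame(
    rec_idx = rep(seq_len(nrow(records)), n),
    frag_id = paste0("f", rep(seq_len(nrow(records)), n), "_",
                     unlist(lapply(n, seq_len))),
    frag_smiles = unlist(frags),
    stringsAsFactors = FALSE
  )
}

# largest organic fragment: prefer carbon-containing, then most heavy atoms,
# ties broken by input order
pick_largest_organic <- function(graphs) {
  heavy <- vapply(graphs, function(g) sum(g$atoms != "H"), 0L)
  has_c <- vapply(graphs, function(g) any(g$atoms == "C"), NA)
  cand <- if (any(has_c)) which(has_c) else seq_along(graphs)
  cand[which.max(heavy[cand])]
}

# run obabel: SMILES lines -> H-explicit SDF, skipping unparsable entries
obabel_smiles_to_sdf <- function(smiles, ids) {
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(smiles, ids), infile)
  status <- suppressWarnings(
    system2("obabel",
            c("-ismi", shQuote(infile), "-osdf", "-O", shQuote(outfile),
              "-h", "-e", "--errorlevel", "0"),
            stdout = FALSE, stderr = FALSE)
  )
  if (!file.exists(outfile) || file.size(outfile) == 0L) {
    empty <- methods::new("SDFset")
    return(empty)
  }
  sdf <- suppressWarnings(ChemmineR::read.SDFset(outfile))
  sdf[ChemmineR::validSDF(sdf)]
}

obabel_sdf_to_cansmi <- function(sdf) {
  infile <- tempfile(fileext = ".sdf")
  outfile <- tempfile(fileext = ".smi")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  ChemmineR::write.SDF(sdf, infile)
  status <- suppressWarnings(
    system2("obabel",
            c("-isdf", shQuote(infile), "-ocan", "-O", shQuote(outfile),
              "-d", "-e", "--errorlevel", "0"),
            stdout = FALSE, stderr = FALSE)
  )
  lines <- readLines(outfile, warn = FALSE)
  vapply(strsplit(trimws(lines), "[[:space:]]+"), `[`, "", 1L)
}

# MW / Wildman-Crippen logP / Ertl TPSA via ChemmineOB
obabel_properties <- function(sdf, ids) {
  props <- tryCatch(ChemmineR::propOB(sdf), error = function(e) {
    stop("descriptor computation failed for molecule '", ids[1], "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (any(!is.finite(props$MW)) || any(props$MW <= 0)) {
    stop("invalid molecular weight for molecule '",
         ids[which(!is.finite(props$MW) | props$MW <= 0)[1]], "'",
         call. = FALSE)
  }
  list(mw = as.numeric(props$MW), logp = as.numeric(props$logP),
       tpsa = as.numeric(props$TPSA))
}

# atom symbols and bond table from a single ChemmineR SDF object
sdf_graph <- function(sdfobj) {
  ab <- ChemmineR::atomblock(sdfobj)
  bb <- ChemmineR::bondblock(sdfobj)
  atoms <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    matrix(integer(0), ncol = 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  list(atoms = atoms, bonds = bonds)
}

# counting descriptors from the H-explicit graph
graph_descriptors <- function(graph) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n_carbon <- sum(atoms == "C")
  n_hetero <- sum(!(atoms %in% c("C", "H")))
  hba <- sum(atoms %in% c("N", "O"))

  if (nrow(bonds) == 0L) {
    return(c(hbd = 0L, hba = hba, n_rotb = 0L, n_carbon = n_carbon,
             n_hetero = n_hetero, n_rings = 0L))
  }

  a1 <- bonds[, 1]; a2 <- bonds[, 2]; order <- bonds[, 3]
  s1 <- atoms[a1]; s2 <- atoms[a2]

  # donors: hydrogens attached to N or O
  hbd <- sum((s1 == "H" & s2 %in% c("N", "O")) |
             (s2 == "H" & s1 %in% c("N", "O")))

  g <- igraph::graph_from_edgelist(cbind(a1, a2), directed = FALSE)
  if (igraph::vcount(g) < length(atoms)) {
    g <- igraph::add_vertices(g, length(atoms) - igraph::vcount(g))
  }
  n_rings <- igraph::ecount(g) - igraph::vcount(g) +
    igraph::count_components(g)

  in_ring <- rep(TRUE, nrow(bonds))
  in_ring[igraph::bridges(g)] <- FALSE

  # heavy-atom degree (number of heavy neighbours per atom)
  heavy_deg <- integer(length(atoms))
  hh <- s1 != "H" & s2 != "H"
  for (idx in which(hh)) {
    heavy_deg[a1[idx]] <- heavy_deg[a1[idx]] + 1L
    heavy_deg[a2[idx]] <- heavy_deg[a2[idx]] + 1L
  }

  # amide C-N: carbon double-bonded to oxygen, single-bonded to nitrogen
  carbonyl_c <- unique(c(a1[order == 2L & s1 == "C" & s2 == "O"],
                         a2[order == 2L & s2 == "C" & s1 == "O"]))
  amide <- (s1 == "C" & s2 == "N" & a1 %in% carbonyl_c) |
           (s2 == "C" & s1 == "N" & a2 %in% carbonyl_c)

  rot <- order == 1L & !in_ring & hh &
    heavy_deg[a1] >= 2L & heavy_deg[a2] >= 2L & !amide
  c(hbd = hbd, hba = hba, n_rotb = sum(rot), n_carbon = n_carbon,
    n_hetero = n_hetero, n_rings = as.integer(n_rings))
}
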