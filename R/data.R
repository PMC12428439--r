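#' Default sampling ranges for the descriptor-space sampler
#'
#' Uniform sampling intervals that bracket every threshold of the built-in
#' rule sets with wide margins, so all violation classes are reachable:
#' mw 50--2000 Da, logP -8--12, HBD 0--30, HBA 0--40, TPSA 0--600 A^2,
#' rotatable bonds 0--50, carbons 1--120, heteroatoms 0--60, rings 0--12.
#' Count descriptors are drawn as integers, the rest as continuous values.
#'
#' @return named list of `c(lower, upper)` ranges.
#' @export
default_descriptor_ranges <- function() {
  list(mw = c(50, 2000), logp = c(-8, 12), hbd = c(0, 30), hba = c(0, 40),
       tpsa = c(0, 600), n_rotb = c(0, 50), n_carbon = c(1, 120),
       n_hetero = c(0, 60), n_rings = c(0, 12))
}

integer_descriptor_keys <- function() {
  c("hbd", "hba", "n_rotb", "n_carbon", "n_hetero", "n_rings")
}

#' Configuration for the descriptor-space sampler
#'
#' @param n number of rows to draw.
#' @param seed RNG seed; a fixed seed yields an identical table.
#' @param ranges per-descriptor sampling intervals
#'   (see [default_descriptor_ranges()]).
#' @param stratify_rule optional: a rule name (`"ro5"`, `"bro5"`,
#'   `"muegge"`) or a `dl_ruleset`. When set, sampling continues until every
#'   violation class `0..max_violations` holds at least
#'   `floor(n / (2 * (max + 1)))` rows.
#' @param max_batches bound on resampling attempts before stratification is
#'   declared unsatisfiable.
#' @return a `dl_sampler_config`.
#' @export
sampler_config <- function(n, seed = 1L, ranges = default_descriptor_ranges(),
                           stratify_rule = NULL, max_batches = 500L) {
  if (!is.numeric(n) || length(n) != 1L || n < 0) {
    stop("'n' must be a non-negative count", call. = FALSE)
  }
  rs <- NULL
  if (!is.null(stratify_rule)) {
    rs <- if (inherits(stratify_rule, "dl_ruleset")) stratify_rule else
      builtin_ruleset(stratify_rule)
    missing <- setdiff(rs$criteria$descriptor_key, names(ranges))
    if (length(missing) > 0L) {
      stop("sampler ranges do not cover descriptor '", missing[1],
           "' referenced by rule '", rs$name, "'", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), seed = as.integer(seed), ranges = ranges,
                 stratify_ruleset = rs, max_batches = as.integer(max_batches)),
            class = "dl_sampler_config")
}

draw_batch <- function(n, ranges) {
  cols <- lapply(names(ranges), function(k) {
    r <- ranges[[k]]
    if (k %in% integer_descriptor_keys()) {
      sample.int(as.integer(r[2]) - as.integer(r[1]) + 1L, n,
                 replace = TRUE) + as.integer(r[1]) - 1L
    } else {
      stats::runif(n, r[1], r[2])
    }
  })
  names(cols) <- names(ranges)
  as.data.frame(cols)
}

#' Draw a synthetic descriptor table
#'
#' Samples descriptor vectors independently and uniformly from the
#' configured ranges. With `stratify_rule` set, rows of under-represented
#' violation classes are accumulated over additional batches (adaptively
#' sized from the observed class rates, memory-bounded: only rows of
#' still-deficient classes are retained) until every class `0..max` holds at
#' least `floor(n / (2 * (max + 1)))` rows; the final table interleaves the
#' per-class quota with the remaining draws in draw order.
#'
#' @param cfg a [sampler_config()].
#' @return data.frame with column `id` plus one column per configured
#'   descriptor; with stratification, an integer attribute-free label column
#'   is *not* included (labels are recomputed by the counters downstream).
#' @export
sample_descriptor_vectors <- function(cfg) {
  stopifnot(inherits(cfg, "dl_sampler_config"))
  n <- cfg$n
  if (n == 0L) {
    out <- draw_batch(0L, cfg$ranges)
    return(cbind(data.frame(id = character(0)), out))
  }
  tab <- withr::with_seed(cfg$seed, sample_stratified(cfg))
  tab$id <- sprintf("s%06d", seq_len(nrow(tab)))
  tab[c("id", names(cfg$ranges))]
}

sample_stratified <- function(cfg) {
  n <- cfg$n
  rs <- cfg$stratify_ruleset
  if (is.null(rs)) return(draw_batch(n, cfg$ranges))

  maxv <- max_violations(rs)
  minc <- n %/% (2L * (maxv + 1L))
  b <- draw_batch(n, cfg$ranges)
  y <- count_violations_table(b, rs)
  pool <- list(b)
  pool_y <- list(y)
  tally <- tabulate(y + 1L, maxv + 1L)
  drawn <- n
  batch <- n
  attempts <- 0L
  while (!all(tally >= minc)) {
    attempts <- attempts + 1L
    if (attempts > cfg$max_batches) {
      stop("stratification on rule '", rs$name, "' unsatisfied after ",
           cfg$max_batches, " batches; classes ",
           paste(which(tally < minc) - 1L, collapse = ","),
           " remain under-represented under the given ranges",
           call. = FALSE)
    }
    deficient <- which(tally < minc) - 1L
    b <- draw_batch(batch, cfg$ranges)
    y <- count_violations_table(b, rs)
    drawn <- drawn + batch
    sel <- y %in% deficient
    if (any(sel)) {
      b <- b[sel, , drop = FALSE]
      y <- y[sel]
      keep <- unlist(lapply(deficient, function(cl) {
        utils::head(which(y == cl), minc - tally[cl + 1L])
      }))
      keep <- sort(keep)
      pool[[length(pool) + 1L]] <- b[keep, , drop = FALSE]
      pool_y[[length(pool_y) + 1L]] <- y[keep]
      tally <- tally + tabulate(y[keep] + 1L, maxv + 1L)
    }
    # size the next batch from the rarest still-deficient class rate
    rate <- pmax(tally / drawn, 1 / drawn)
    need <- max((minc - tally) / rate)
    batch <- as.integer(min(2e6, max(n, ceiling(need * 1.3))))
  }
  all_rows <- do.call(rbind, pool)
  all_y <- unlist(pool_y)
  idx <- seq_len(nrow(all_rows))
  quota <- unlist(lapply(0:maxv, function(cl) {
    utils::head(idx[all_y == cl], minc)
  }))
  rest <- utils::head(setdiff(idx, quota), n - length(quota))
  out <- all_rows[c(quota, rest), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- labelled datasets -----------------------------------------------------

as_ruleset_list <- function(rulesets) {
  if (inherits(rulesets, "dl_ruleset")) rulesets <- list(rulesets)
  if (!is.list(rulesets) || length(rulesets) == 0L ||
      !all(vapply(rulesets, inherits, NA, "dl_ruleset"))) {
    stop("'rulesets' must be a dl_ruleset or a non-empty list of them",
         call. = FALSE)
  }
  nm <- vapply(rulesets, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate rule name '", nm[duplicated(nm)][1], "'", call. = FALSE)
  }
  stats::setNames(rulesets, nm)
}

rule_info_list <- function(rulesets) {
  lapply(rulesets, function(rs) {
    list(variant = rs$variant, max_violations = max_violations(rs),
         thresholds_fingerprint = thresholds_fingerprint(rs))
  })
}

new_dataset <- function(representation, feature_names, features, targets,
                        ids, rule_info, provenance) {
  structure(list(representation = representation,
                 feature_names = feature_names, features = features,
                 targets = targets, ids = ids, rule_info = rule_info,
                 provenance = provenance),
            class = "dl_dataset")
}

#' @export
print.dl_dataset <- function(x, ...) {
  cat("<labelled dataset> ", length(x$ids), " rows x ",
      length(x$feature_names), " ", x$representation, " features; rules: ",
      paste(names(x$targets), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of rows of a labelled dataset
#' @param ds a `dl_dataset`.
#' @return integer.
#' @export
dataset_nrow <- function(ds) length(ds$ids)

dataset_slice <- function(ds, idx) {
  new_dataset(ds$representation, ds$feature_names,
              ds$features[idx, , drop = FALSE],
              lapply(ds$targets, `[`, idx), ds$ids[idx], ds$rule_info,
              ds$provenance)
}

#' Build a labelled dataset from molecules
#'
#' Parses the molecules, computes descriptors, labels every molecule with
#' each rule set's violation counter, and assembles the feature matrix in
#' the requested representation. Targets are always computed from the
#' descriptor vector, also under the fingerprint representation, so the two
#' representations of the same molecules carry identical labels. Parse
#' failures are reported via a warning and the `failures` attribute, never
#' silently dropped.
#'
#' @param records molecule records (data.frame with `id`, `smiles`).
#' @param rulesets a `dl_ruleset` or list of them.
#' @param representation `"descriptors"` or `"fingerprints"`.
#' @param fp_params fingerprint parameters,
#'   `list(radius = 2, n_bits = 2048)`.
#' @return a `dl_dataset`.
#' @export
build_labelled_dataset <- function(records, rulesets,
                                   representation = c("descriptors",
                                                      "fingerprints"),
                                   fp_params = list(radius = 2L,
                                                    n_bits = 2048L)) {
  representation <- match.arg(representation)
  rulesets <- as_ruleset_list(rulesets)
  molset <- parse_molecules(records)
  if (nrow(molset$failures) > 0L) {
    warning(nrow(molset$failures), " molecule(s) failed to parse (first: '",
            molset$failures$id[1], "')", call. = FALSE)
  }
  desc <- descriptor_table(molset)
  targets <- lapply(rulesets, function(rs) count_violations_table(desc, rs))
  if (representation == "descriptors") {
    features <- desc[descriptor_keys()]
    feature_names <- descriptor_keys()
  } else {
    fm <- fingerprint_matrix(molset, radius = fp_params$radius,
                             n_bits = fp_params$n_bits)
    features <- as.data.frame(fm)
    feature_names <- colnames(fm)
  }
  rownames(features) <- NULL
  ds <- new_dataset(representation, feature_names, features, targets,
                    desc$id, rule_info_list(rulesets),
                    provenance = list(
                      source = "molecules",
                      estimators = list(logp = "openbabel_wildman_crippen",
                                        tpsa = "openbabel_ertl"),
                      fp_params = if (representation == "fingerprints")
                        fp_params else NULL,
                      n_parse_failures = nrow(molset$failures)))
  attr(ds, "failures") <- molset$failures
  ds
}

#' Build a labelled dataset from a descriptor table
#'
#' Labels precomputed (or sampled) descriptor rows with the rule counters,
#' enabling descriptor-space training without any SMILES input.
#'
#' @param table data.frame holding every descriptor column the rule sets
#'   reference; an `id` column is used if present.
#' @param rulesets a `dl_ruleset` or list of them.
#' @return a `dl_dataset` with descriptor representation.
#' @export
build_dataset_from_descriptor_table <- function(table, rulesets) {
  rulesets <- as_ruleset_list(rulesets)
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("descriptor table is empty", call. = FALSE)
  }
  feature_names <- intersect(descriptor_keys(), names(table))
  for (rs in rulesets) {
    missing <- setdiff(rs$criteria$descriptor_key, feature_names)
    if (length(missing) > 0L) {
      stop("descriptor column '", missing[1], "' missing (rule '", rs$name,
           "')", call. = FALSE)
    }
  }
  ids <- if ("id" %in% names(table)) as.character(table$id) else
    sprintf("s%06d", seq_len(nrow(table)))
  targets <- lapply(rulesets, function(rs) count_violations_table(table, rs))
  features <- table[feature_names]
  rownames(features) <- NULL
  new_dataset("descriptors", feature_names, features, targets, ids,
              rule_info_list(rulesets),
              provenance = list(source = "descriptor_table"))
}

#' Train/test split specification
#'
#' @param test_fraction proportion of rows held out, in (0, 1).
#' @param seed RNG seed for the row permutation.
#' @return a `dl_split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, seed = 42L) {
  if (!is.numeric(test_fraction) || length(test_fraction) != 1L ||
      test_fraction <= 0 || test_fraction >= 1) {
    stop("'test_fraction' must lie in (0, 1)", call. = FALSE)
  }
  structure(list(test_fraction = test_fraction, seed = as.integer(seed)),
            class = "dl_split_spec")
}

#' Split a labelled dataset into train and test parts
#'
#' Draws `round(n * test_fraction)` rows as the held-out set under the
#' spec's seed; the same dataset and spec always produce the identical
#' partition.
#'
#' @param ds a `dl_dataset`.
#' @param spec a [split_spec()]; defaults to 20% held out, seed 42.
#' @return list with elements `train` and `test`, both `dl_dataset`s whose
#'   provenance records the split.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "dl_dataset"), inherits(spec, "dl_split_spec"))
  n <- dataset_nrow(ds)
  n_test <- round(n * spec$test_fraction)
  if (n_test < 1L || n_test > n - 1L) {
    stop("cannot split ", n, " rows into non-empty train and test parts ",
         "at test_fraction = ", spec$test_fraction, call. = FALSE)
  }
  test_idx <- withr::with_seed(spec$seed, sample.int(n, n_test))
  train <- dataset_slice(ds, setdiff(seq_len(n), test_idx))
  test <- dataset_slice(ds, test_idx)
  train$provenance$split <- list(part = "train",
                                 test_fraction = spec$test_fraction,
                                 seed = spec$seed)
  test$provenance$split <- list(part = "test",
                                test_fraction = spec$test_fraction,
                                seed = spec$seed)
  list(train = train, test = test)
}

## ---- dataset CSV round-trip ------------------------------------------------

pack_bits_hex <- function(bits) {
  stopifnot(length(bits) %% 4L == 0L)
  nib <- matrix(bits, nrow = 4L)
  vals <- as.integer(8L * nib[1L, ] + 4L * nib[2L, ] + 2L * nib[3L, ] +
                       nib[4L, ])
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

unpack_bits_hex <- function(hex, n_bits) {
  vals <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  bits <- unlist(lapply(vals, function(v) {
    c(bitwAnd(v, 8L) > 0L, bitwAnd(v, 4L) > 0L, bitwAnd(v, 2L) > 0L,
      bitwAnd(v, 1L) > 0L)
  }))
  as.integer(bits[seq_len(n_bits)])
}

#' Write a labelled dataset to CSV with a JSON provenance sidecar
#'
#' Descriptor features are written as plain columns; fingerprint rows are
#' packed into a hex string column (`fp_hex`) to keep files compact. Targets
#' appear as `y_<rule>` columns. A `<path>.meta.json` sidecar records the
#' representation, feature names, rule variants, thresholds fingerprints and
#' provenance needed for an exact round-trip.
#'
#' @param ds a `dl_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "dl_dataset"))
  if (ds$representation == "descriptors") {
    out <- cbind(data.frame(id = ds$ids, stringsAsFactors = FALSE),
                 ds$features)
  } else {
    hex <- apply(as.matrix(ds$features), 1L, pack_bits_hex)
    out <- data.frame(id = ds$ids, fp_hex = hex, stringsAsFactors = FALSE)
  }
  for (rule in names(ds$targets)) out[[paste0("y_", rule)]] <-
    ds$targets[[rule]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(representation = ds$representation,
               feature_names = ds$feature_names,
               n_bits = if (ds$representation == "fingerprints")
                 length(ds$feature_names) else NULL,
               rule_info = ds$rule_info, provenance = ds$provenance)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a labelled dataset written by [write_dataset_csv()]
#'
#' @param path CSV path (the `<path>.meta.json` sidecar must sit next to
#'   it).
#' @return a `dl_dataset`.
#' @export
read_dataset_csv <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("missing dataset sidecar '", meta_path, "'", call. = FALSE)
  }
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  target_cols <- grep("^y_", names(df), value = TRUE)
  targets <- lapply(target_cols, function(cl) as.integer(df[[cl]]))
  names(targets) <- sub("^y_", "", target_cols)
  if (meta$representation == "descriptors") {
    features <- df[meta$feature_names]
  } else {
    n_bits <- as.integer(meta$n_bits)
    m <- t(vapply(df$fp_hex, unpack_bits_hex, integer(n_bits),
                  n_bits = n_bits))
    colnames(m) <- meta$feature_names
    features <- as.data.frame(m)
  }
  rownames(features) <- NULL
  new_dataset(meta$representation, meta$feature_names, features, targets,
              as.character(df$id), meta$rule_info, meta$provenance)
}

## ---- peptide assembler -----------------------------------------------------

#' Residue fragment table for the peptide assembler
#'
#' The 20 proteinogenic amino acids as backbone SMILES fragments of the form
#' `N[C@@H](sidechain)C(=O)` (glycine and proline use their specific
#' backbones). Concatenating fragments and capping with a hydroxyl yields a
#' linear peptide SMILES.
#'
#' @return named character vector, one fragment per one-letter residue code.
#' @export
peptide_alphabet <- function() {
  c(G = "NCC(=O)",
    A = "N[C@@H](C)C(=O)",
    V = "N[C@@H](C(C)C)C(=O)",
    L = "N[C@@H](CC(C)C)C(=O)",
    I = "N[C@@H]([C@@H](C)CC)C(=O)",
    P = "N1CCC[C@H]1C(=O)",
    F = "N[C@@H](Cc1ccccc1)C(=O)",
    W = "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)",
    M = "N[C@@H](CCSC)C(=O)",
    S = "N[C@@H](CO)C(=O)",
    T = "N[C@@H]([C@@H](O)C)C(=O)",
    C = "N[C@@H](CS)C(=O)",
    Y = "N[C@@H](Cc1ccc(O)cc1)C(=O)",
    N = "N[C@@H](CC(N)=O)C(=O)",
    Q = "N[C@@H](CCC(N)=O)C(=O)",
    D = "N[C@@H](CC(=O)O)C(=O)",
    E = "N[C@@H](CCC(=O)O)C(=O)",
    K = "N[C@@H](CCCCN)C(=O)",
    R = "N[C@@H](CCCNC(=N)N)C(=O)",
    H = "N[C@@H](Cc1cnc[nH]1)C(=O)")
}

#' Assemble a linear peptide SMILES
#'
#' Concatenates residue backbone fragments and caps the C-terminus with a
#' hydroxyl. With `residues` given, that exact sequence is built; otherwise
#' `length` residues are drawn uniformly from the alphabet under `seed`.
#'
#' @param length residue count (>= 1); ignored when `residues` is given.
#' @param alphabet residue table, see [peptide_alphabet()].
#' @param seed RNG seed for the random sequence.
#' @param residues optional character vector (or single string) of residue
#'   codes.
#' @param id record identifier.
#' @return one-row data.frame with columns `id`, `smiles`, `name` (the
#'   residue sequence); the SMILES is guaranteed parseable by
#'   [parse_molecule()].
#' @examples
#' generate_peptide_smiles(residues = "G")$smiles  # "NCC(=O)O"
#' @export
generate_peptide_smiles <- function(length = 1L,
                                    alphabet = peptide_alphabet(),
                                    seed = 1L, residues = NULL,
                                    id = "pep1") {
  if (is.null(residues)) {
    if (!is.numeric(length) || length < 1L) {
      stop("'length' must be >= 1", call. = FALSE)
    }
    residues <- withr::with_seed(seed,
      sample(names(alphabet), as.integer(length), replace = TRUE))
  } else {
    if (is.character(residues) && length(residues) == 1L &&
        nchar(residues) > 1L) {
      residues <- strsplit(residues, "")[[1]]
    }
    unknown <- setdiff(residues, names(alphabet))
    if (length(unknown) > 0L) {
      stop("unknown residue code '", unknown[1], "'", call. = FALSE)
    }
  }
  smiles <- paste0(paste(alphabet[residues], collapse = ""), "O")
  data.frame(id = id, smiles = smiles,
             name = paste(residues, collapse = ""), stringsAsFactors = FALSE)
}

#' Generate a set of random linear peptides
#'
#' @param n number of peptides.
#' @param lengths residue-count range, `c(min, max)`; each peptide's length
#'   is drawn uniformly.
#' @param alphabet residue table.
#' @param seed RNG seed.
#' @return data.frame of molecule records (`id`, `smiles`, `name`).
#' @export
generate_peptide_set <- function(n, lengths = c(2L, 16L),
                                 alphabet = peptide_alphabet(), seed = 1L) {
  stopifnot(n >= 1L)
  withr::with_seed(seed, {
    lens <- sample(seq.int(lengths[1], lengths[2]), n, replace = TRUE)
    recs <- lapply(seq_len(n), function(i) {
      res <- sample(names(alphabet), lens[i], replace = TRUE)
      generate_peptide_smiles(residues = res,
                              id = sprintf("pep%04d", i))
    })
  })
  do.call(rbind, recs)
}
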