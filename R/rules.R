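#' Construct a single rule criterion
#'
#' A criterion is an inclusive interval over one descriptor. A molecule
#' complies when `lower <= value <= upper` (missing bounds are open);
#' violations are strict inequalities, so a value sitting exactly on a bound
#' is compliant.
#'
#' @param descriptor_key one of the descriptor names
#'   (`mw, logp, hbd, hba, tpsa, n_rotb, n_carbon, n_hetero, n_rings`).
#' @param lower,upper inclusive bounds; at least one must be given.
#' @param label human-readable name; defaults to an interval rendering.
#' @return a one-row data.frame (the criterion).
#' @export
rule_criterion <- function(descriptor_key, lower = NA_real_,
                           upper = NA_real_, label = NULL) {
  if (!descriptor_key %in% descriptor_keys()) {
    stop("unknown descriptor key '", descriptor_key, "'", call. = FALSE)
  }
  if (is.na(lower) && is.na(upper)) {
    stop("criterion on '", descriptor_key, "' needs at least one bound",
         call. = FALSE)
  }
  if (!is.na(lower) && !is.na(upper) && lower > upper) {
    stop("lower bound exceeds upper bound for '", descriptor_key, "'",
         call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (is.na(lower)) {
      paste0(descriptor_key, " <= ", upper)
    } else if (is.na(upper)) {
      paste0(descriptor_key, " >= ", lower)
    } else {
      paste0(lower, " <= ", descriptor_key, " <= ", upper)
    }
  }
  data.frame(descriptor_key = descriptor_key, lower = as.numeric(lower),
             upper = as.numeric(upper), label = label,
             stringsAsFactors = FALSE)
}

new_ruleset <- function(name, variant, criteria) {
  structure(list(name = name, variant = variant, criteria = criteria),
            class = "dl_ruleset")
}

#' Built-in drug-likeness rule sets
#'
#' Returns one of the three canonical rule sets as data:
#'
#' * `ro5` -- Lipinski's Rule of Five: Mw <= 500 Da, logP in \[0, 5\],
#'   HBD <= 5, HBA <= 10 (4 criteria). The lower logP bound is part of the
#'   rule as stated here; `ro5_logp_lower = FALSE` drops it to reproduce the
#'   convention of platforms that only penalise logP > 5.
#' * `bro5` -- the beyond-Ro5 peptide extension: Mw <= 1000 Da, logP in
#'   \[-2, 10\], HBD <= 6, HBA <= 15, TPSA <= 250 A^2, rotatable bonds <= 20
#'   (6 criteria).
#' * `muegge` -- Muegge's drug-likeness criteria. The default `core6`
#'   variant keeps the six property criteria (Mw in \[200, 600\], logP in
#'   \[-2, 5\], TPSA <= 150, rotatable bonds <= 15, HBA <= 10, HBD <= 5);
#'   the `full` variant adds the topological/elemental checks
#'   (rings <= 7, carbons > 4, heteroatoms > 1; 9 criteria), which is what
#'   SwissADME evaluates.
#'
#' @param name `"ro5"`, `"bro5"` or `"muegge"`.
#' @param ro5_logp_lower keep the logP >= 0 criterion of `ro5` (default TRUE).
#' @param muegge_variant `"core6"` (default) or `"full"`.
#' @return a `dl_ruleset`.
#' @examples
#' builtin_ruleset("ro5")
#' max_violations(builtin_ruleset("muegge", muegge_variant = "full"))
#' @export
builtin_ruleset <- function(name, ro5_logp_lower = TRUE,
                            muegge_variant = c("core6", "full")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("ro5", "bro5", "muegge")) {
    stop("unknown rule set '", paste(name, collapse = ","),
         "'; expected one of: ro5, bro5, muegge", call. = FALSE)
  }
  switch(name,
    ro5 = {
      logp <- if (isTRUE(ro5_logp_lower)) {
        rule_criterion("logp", 0, 5)
      } else {
        rule_criterion("logp", upper = 5)
      }
      new_ruleset("ro5",
                  if (isTRUE(ro5_logp_lower)) "logp_lower_on" else
                    "logp_lower_off",
                  rbind(rule_criterion("mw", upper = 500), logp,
                        rule_criterion("hbd", upper = 5),
                        rule_criterion("hba", upper = 10)))
    },
    bro5 = new_ruleset("bro5", "standard",
                       rbind(rule_criterion("mw", upper = 1000),
                             rule_criterion("logp", -2, 10),
                             rule_criterion("hbd", upper = 6),
                             rule_criterion("hba", upper = 15),
                             rule_criterion("tpsa", upper = 250),
                             rule_criterion("n_rotb", upper = 20))),
    muegge = {
      muegge_variant <- match.arg(muegge_variant)
      core <- rbind(rule_criterion("mw", 200, 600),
                    rule_criterion("logp", -2, 5),
                    rule_criterion("tpsa", upper = 150),
                    rule_criterion("n_rotb", upper = 15),
                    rule_criterion("hba", upper = 10),
                    rule_criterion("hbd", upper = 5))
      crit <- if (muegge_variant == "full") {
        rbind(core,
              rule_criterion("n_rings", upper = 7),
              rule_criterion("n_carbon", lower = 5, label = "n_carbon > 4"),
              rule_criterion("n_hetero", lower = 2, label = "n_hetero > 1"))
      } else {
        core
      }
      new_ruleset("muegge", muegge_variant, crit)
    }
  )
}

#' Maximum possible violation count of a rule set
#' @param rs a `dl_ruleset`.
#' @return integer, the number of criteria.
#' @export
max_violations <- function(rs) {
  stopifnot(inherits(rs, "dl_ruleset"))
  nrow(rs$criteria)
}

#' @export
print.dl_ruleset <- function(x, ...) {
  cat("<rule set '", x$name, "' (", x$variant, "), ", nrow(x$criteria),
      " criteria>\n", sep = "")
  for (i in seq_len(nrow(x$criteria))) cat("  - ", x$criteria$label[i], "\n",
                                           sep = "")
  invisible(x)
}

#' Count rule violations for one descriptor vector
#'
#' A criterion is violated iff the descriptor value falls strictly below its
#' lower bound or strictly above its upper bound; boundary values comply.
#'
#' @param dv named numeric vector (or one-row data.frame) carrying every
#'   descriptor the rule set references.
#' @param rs a `dl_ruleset`.
#' @return list with `count` (integer) and `flags` (named logical vector,
#'   TRUE = violated, one element per criterion).
#' @examples
#' dv <- c(mw = 400, logp = 2, hbd = 3, hba = 8)
#' count_violations(dv, builtin_ruleset("ro5"))$count  # 0
#' @export
count_violations <- function(dv, rs) {
  stopifnot(inherits(rs, "dl_ruleset"))
  if (is.data.frame(dv)) {
    if (nrow(dv) != 1L) {
      stop("'dv' must be a single descriptor vector; use ",
           "count_violations_table() for tables", call. = FALSE)
    }
    dv <- unlist(dv[vapply(dv, is.numeric, NA)])
  }
  crit <- rs$criteria
  missing <- setdiff(crit$descriptor_key, names(dv))
  if (length(missing) > 0L) {
    stop("descriptor '", missing[1], "' missing from input (rule '",
         rs$name, "')", call. = FALSE)
  }
  x <- as.numeric(dv[crit$descriptor_key])
  if (any(is.na(x))) {
    stop("descriptor '",
         crit$descriptor_key[which(is.na(x))[1]],
         "' is NA (rule '", rs$name, "')", call. = FALSE)
  }
  flags <- (!is.na(crit$lower) & x < crit$lower) |
           (!is.na(crit$upper) & x > crit$upper)
  names(flags) <- crit$label
  list(count = as.integer(sum(flags)), flags = flags)
}

#' Vectorised violation counts over a descriptor table
#'
#' @param table data.frame with one column per descriptor the rule set
#'   references.
#' @param rs a `dl_ruleset`.
#' @return integer vector of violation counts, one per row.
#' @export
count_violations_table <- function(table, rs) {
  stopifnot(inherits(rs, "dl_ruleset"))
  crit <- rs$criteria
  missing <- setdiff(crit$descriptor_key, names(table))
  if (length(missing) > 0L) {
    stop("descriptor column '", missing[1], "' missing (rule '", rs$name,
         "')", call. = FALSE)
  }
  v <- integer(nrow(table))
  for (i in seq_len(nrow(crit))) {
    x <- table[[crit$descriptor_key[i]]]
    if (any(is.na(x))) {
      stop("NA in descriptor column '", crit$descriptor_key[i], "'",
           call. = FALSE)
    }
    v <- v + as.integer((!is.na(crit$lower[i]) & x < crit$lower[i]) |
                        (!is.na(crit$upper[i]) & x > crit$upper[i]))
  }
  v
}

#' Classical Ro5 pass/fail heuristic
#'
#' Lipinski's rule deems a molecule likely orally bioavailable when it
#' violates at most one criterion. Provided as a derived convenience; the
#' models in this package predict counts, not this boolean.
#'
#' @param count integer violation count(s).
#' @return logical vector.
#' @export
ro5_pass <- function(count) count <= 1L

## ---- serialization ---------------------------------------------------------

#' Serialize a rule set to JSON
#' @param rs a `dl_ruleset`.
#' @return a JSON string.
#' @export
ruleset_json <- function(rs) {
  stopifnot(inherits(rs, "dl_ruleset"))
  crit <- lapply(seq_len(nrow(rs$criteria)), function(i) {
    row <- rs$criteria[i, ]
    list(descriptor_key = row$descriptor_key,
         lower = if (is.na(row$lower)) NULL else row$lower,
         upper = if (is.na(row$upper)) NULL else row$upper,
         label = row$label)
  })
  jsonlite::toJSON(list(name = rs$name, variant = rs$variant,
                        criteria = crit),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' Deserialize a rule set from JSON
#' @param json a JSON string or file path.
#' @return a `dl_ruleset`.
#' @export
ruleset_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  crit <- do.call(rbind, lapply(obj$criteria, function(cr) {
    rule_criterion(cr$descriptor_key,
                   lower = if (is.null(cr$lower)) NA_real_ else cr$lower,
                   upper = if (is.null(cr$upper)) NA_real_ else cr$upper,
                   label = cr$label)
  }))
  if (is.null(crit) || nrow(crit) == 0L) {
    stop("rule set has no criteria", call. = FALSE)
  }
  new_ruleset(obj$name, obj$variant, crit)
}

#' Stable fingerprint of a rule set's thresholds
#'
#' MD5 of the canonical JSON serialization; embedded in dataset and model
#' metadata so a model can refuse labels produced under different
#' thresholds.
#'
#' @param rs a `dl_ruleset`.
#' @return a 32-character hex string.
#' @export
thresholds_fingerprint <- function(rs) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(ruleset_json(rs)), tmp)
  unname(tools::md5sum(tmp))
}
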