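## DRE/CRT vs GCC-box binding-capability prediction from the
## position-9/13/14/15 residue signature.  The default rule table is a
## conservative encoding of the cross-species binding-assay compilation:
## S9 DREBs bind DRE/CRT; N/Q/K/T/I9-V14-S15 DREBs prefer DRE/CRT;
## other V14 DREBs (incl. D9 CBFs, flagged low-confidence) can bind both;
## H9 proteins bind the GCC box; P9-A14-A15 ERFs bind the GCC box strongly
## and mostly also DRE/CRT; other P9 proteins are both-capable.  pos13 is
## recorded in the signature but gates no default rule.

.DEFAULT_BINDING_RULES <- list(
  list(name = "S9_V14_DRE",        pos9 = "S",
       pos14 = c("V", "I"), pos15 = NULL, category = "DRE_preferring"),
  list(name = "NQKTI9_V14_S15_DRE", pos9 = c("N", "Q", "K", "T", "I"),
       pos14 = c("V", "I"), pos15 = "S",  category = "DRE_preferring"),
  list(name = "NQKTID9_V14_both",  pos9 = c("N", "Q", "K", "T", "I", "D"),
       pos14 = c("V", "I"), pos15 = NULL, category = "both_capable"),
  list(name = "H9_GCC",            pos9 = "H",
       pos14 = NULL,        pos15 = NULL, category = "GCC_preferring"),
  list(name = "P9_A14_A15_GCC_strong", pos9 = "P",
       pos14 = "A",         pos15 = "A",  category = "both_capable"),
  list(name = "P9_both",           pos9 = "P",
       pos14 = NULL,        pos15 = NULL, category = "both_capable"))

#' Default binding-capability rule table
#'
#' Rules are tried in order; the first whose residue sets all match fires.
#' A `NULL` position set matches any residue.  The table ships as editable
#' YAML (see [readBindingRules()]) so users can tighten or extend it as new
#' binding evidence accumulates.
#'
#' @return list of rules, each with `name`, `pos9`, `pos14`, `pos15`
#'   (character vectors or `NULL`) and `category`.
#' @export
defaultBindingRules <- function() .DEFAULT_BINDING_RULES

#' Read a binding rule table from YAML
#'
#' @param path YAML file: a list of rules with fields `name`, `category`
#'   and optional `pos9`/`pos14`/`pos15` residue lists.
#' @return rule list in the [defaultBindingRules()] format.
#' @export
readBindingRules <- function(path) {
  rules <- read_yaml(path)
  lapply(rules, function(r) {
    stopifnot(!is.null(r$name), !is.null(r$category))
    list(name = r$name,
         pos9 = if (length(r$pos9)) as.character(r$pos9),
         pos14 = if (length(r$pos14)) as.character(r$pos14),
         pos15 = if (length(r$pos15)) as.character(r$pos15),
         category = r$category)
  })
}

#' Predict DRE/CRT vs GCC-box binding capability
#'
#' Applies the rule table to each protein's position-9/13/14/15 signature.
#' Exactly one rule fires (the first match); signatures matching no rule
#' are `unknown`.  Total over all standard-residue signatures: never errors
#' on valid letters.
#'
#' @param keyResidues data.frame from [extractKeyResidues()] (columns
#'   `protein_id`, `pos9`, `pos13`, `pos14`, `pos15`).
#' @param rules rule table (default [defaultBindingRules()]).
#' @return data.frame with columns `protein_id`, `signature`
#'   (`"pos9-pos13-pos14-pos15"`), `category`, `rule_fired`.
#' @export
predictBinding <- function(keyResidues, rules = defaultBindingRules()) {
  kr <- keyResidues
  needed <- c("pos9", "pos14", "pos15")
  for (p in needed)
    if (any(kr[[p]] == "-"))
      stop("missing residue at ", p, " for: ",
           paste(kr$protein_id[kr[[p]] == "-"], collapse = ", "))
  one <- function(i) {
    for (r in rules) {
      if (!is.null(r$pos9) && !(kr$pos9[i] %in% r$pos9)) next
      if (!is.null(r$pos14) && !(kr$pos14[i] %in% r$pos14)) next
      if (!is.null(r$pos15) && !(kr$pos15[i] %in% r$pos15)) next
      return(c(r$category, r$name))
    }
    c("unknown", "none")
  }
  hitm <- t(vapply(seq_len(nrow(kr)), one, character(2)))
  data.frame(protein_id = kr$protein_id,
             signature = paste(kr$pos9, kr$pos13, kr$pos14, kr$pos15,
                               sep = "-"),
             category = hitm[, 1], rule_fired = hitm[, 2],
             stringsAsFactors = FALSE)
}

#' Tabulate binding signatures and categories
#'
#' @param predictions data.frame from [predictBinding()].
#' @return list with `by_signature` and `by_category` count tables
#'   (data.frames, sorted by count descending).
#' @export
tabulateSignatures <- function(predictions) {
  tab <- function(x, nm) {
    if (!length(x)) return(setNames(data.frame(character(), integer()),
                                    c(nm, "n")))
    t <- as.data.frame(table(x), stringsAsFactors = FALSE)
    names(t) <- c(nm, "n")
    t[order(-t$n, t[[nm]]), , drop = FALSE]
  }
  list(by_signature = tab(predictions$signature, "signature"),
       by_category = tab(predictions$category, "category"))
}
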