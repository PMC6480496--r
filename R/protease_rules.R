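#' Load protease rules from a rules file
#'
#' The rules file is a plain-text tab-separated table with header columns
#' `name`, `ec`, `p1`, `p1_prime`, `exceptions`, `notes`. `p1` and
#' `p1_prime` are strings of one-letter residue codes (`.` for the empty
#' set, meaning any residue); `exceptions` is a comma-separated list of
#' blocking `X:Y` pairs (`.` for none). The file is data: reviewable,
#' versioned, and swappable for an alternative transcription of enzyme
#' specificities.
#'
#' @param path Path to the rules file; default: the bundled file.
#' @return A named list of [protease_rule()] objects, in file order.
#' @export
load_protease_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "protease_rules.tsv", package = "biopepsim",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("rules file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  required <- c("name", "ec", "p1", "p1_prime", "exceptions", "notes")
  if (!all(required %in% names(df))) {
    stop("rules file must have header columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  split_set <- function(s) {
    if (is.na(s) || s == "." || s == "") character() else
      strsplit(s, "", fixed = TRUE)[[1L]]
  }
  split_exc <- function(s) {
    if (is.na(s) || s == "." || s == "") character() else
      strsplit(s, ",", fixed = TRUE)[[1L]]
  }
  rules <- lapply(seq_len(nrow(df)), function(i) {
    protease_rule(
      name = df$name[i], ec = df$ec[i],
      p1 = split_set(df$p1[i]), p1_prime = split_set(df$p1_prime[i]),
      exceptions = split_exc(df$exceptions[i]), notes = df$notes[i]
    )
  })
  names(rules) <- df$name
  rules
}

#' The default digestion battery
#'
#' The standard battery of 15 digestion schemes: the 12 bundled single
#' proteases, the double scheme pepsin (pH > 2) + trypsin, and the two
#' triple schemes adding chymotrypsin A or chymotrypsin C. Combined schemes
#' act simultaneously (union of cleavage sites).
#'
#' @param rules Named list of [protease_rule()] objects; default: the
#'   bundled rules file.
#' @return A list of 15 [digestion_scheme()] objects.
#' @export
default_battery <- function(rules = load_protease_rules()) {
  singles <- c("pepsin_ph_gt2", "thermolysin", "bromelain", "chymotrypsin_a",
               "chymotrypsin_c", "pancreatic_elastase", "papain",
               "proteinase_k", "trypsin", "ficin", "cathepsin_g", "subtilisin")
  missing <- setdiff(c(singles, "pepsin_ph_gt2", "trypsin",
                       "chymotrypsin_a", "chymotrypsin_c"), names(rules))
  if (length(missing) > 0L) {
    stop("rules file is missing enzyme(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  schemes <- lapply(singles, function(nm) digestion_scheme(rules[[nm]]))
  schemes <- c(schemes, list(
    digestion_scheme(rules[c("pepsin_ph_gt2", "trypsin")]),
    digestion_scheme(rules[c("pepsin_ph_gt2", "trypsin", "chymotrypsin_a")]),
    digestion_scheme(rules[c("pepsin_ph_gt2", "trypsin", "chymotrypsin_c")])
  ))
  schemes
}

#' Build schemes from a comma-separated enzyme specification
#'
#' Convenience for command-line style usage: `"pepsin_ph_gt2,trypsin"` maps
#' to one combined scheme of those enzymes.
#'
#' @param spec Comma-separated enzyme names (1 to 3).
#' @param rules Named list of rules; default: the bundled rules file.
#' @return A [digestion_scheme()].
#' @export
scheme_from_spec <- function(spec, rules = load_protease_rules()) {
  nms <- trimws(strsplit(spec, ",", fixed = TRUE)[[1L]])
  unknown <- setdiff(nms, names(rules))
  if (length(unknown) > 0L) {
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(rules), collapse = ", "), call. = FALSE)
  }
  digestion_scheme(rules[nms])
}
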