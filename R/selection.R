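## Selection expressions.
##
## Grammar (whitespace-tokenized, case-sensitive keywords):
##   expr      := term ('or' term)*
##   term      := factor ('and' factor)*
##   factor    := 'not' factor | '(' expr ')' | primitive
##   primitive := 'entity' <label>     label may contain shell wildcards (*, ?)
##              | 'resid'  <n | a:b | a-b>
##              | 'name'   <atom name, wildcards allowed>
##              | 'all'
## Unresolvable tokens raise a selection error naming the token; an empty
## final result is an error unless allowEmpty = TRUE.

tokenizeSelection <- function(expression) {
  expression <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(expression), "\\s+")[[1]]
  if (!length(toks) || !nzchar(toks[1]))
    selectionError("empty selection expression")
  toks
}

#' Resolve a selection expression to atom ids
#'
#' Selections combine entity labels (with wildcards), residue-id ranges and
#' atom names with \code{and} / \code{or} / \code{not} and parentheses, e.g.
#' \code{"entity receptor and resid 38:44"} or \code{"entity glycan_*"}.
#' Resolution is deterministic (sorted, duplicate-free) and unresolvable
#' tokens are an error, never a silent empty match.
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param expression selection string, or an integer vector of atom ids
#'   (passed through after validation).
#' @param allowEmpty permit an empty result (default FALSE: empty is an
#'   error, since empty selections usually indicate a typo).
#' @return sorted integer vector of atom ids.
#' @examples
#' # resolveSelection(sys, "entity receptor and resid 41")
#' @export
resolveSelection <- function(system, expression, allowEmpty = FALSE) {
  at <- system@atoms
  if (is.numeric(expression)) {
    ids <- sort(unique(as.integer(expression)))
    bad <- setdiff(ids, at$atom_id)
    if (length(bad))
      selectionError("unknown atom ids: %s", paste(head(bad, 5), collapse = ", "))
    return(ids)
  }
  toks <- tokenizeSelection(expression)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  ent_of_atom <- system@residues$entity[match(at$residue_id,
                                              system@residues$residue_id)]

  parse_primitive <- function() {
    t <- advance()
    if (is.na(t)) selectionError("unexpected end of selection expression")
    if (t == "(") {
      v <- parse_expr()
      if (!identical(advance(), ")"))
        selectionError("unbalanced parentheses in selection")
      return(v)
    }
    if (t == "all") return(rep(TRUE, nrow(at)))
    if (t == "entity") {
      lab <- advance()
      if (is.na(lab)) selectionError("'entity' needs a label")
      if (grepl("[*?]", lab)) {
        hit <- grepl(utils::glob2rx(lab), unique(system@residues$entity))
        if (!any(hit))
          selectionError("entity pattern '%s' matches no entity", lab)
        labs <- unique(system@residues$entity)[hit]
        return(ent_of_atom %in% labs)
      }
      if (!lab %in% system@residues$entity)
        selectionError("unknown entity '%s'", lab)
      return(ent_of_atom == lab)
    }
    if (t == "resid") {
      spec <- advance()
      if (is.na(spec)) selectionError("'resid' needs a residue id or range")
      if (grepl("^-?[0-9]+[:-][0-9]+$", spec)) {
        ab <- as.integer(strsplit(spec, "[:-]")[[1]])
        ids <- seq(ab[1], ab[2])
      } else if (grepl("^-?[0-9]+$", spec)) {
        ids <- as.integer(spec)
      } else selectionError("cannot parse residue spec '%s'", spec)
      if (!any(ids %in% system@residues$residue_id))
        selectionError("residue spec '%s' matches no residue", spec)
      return(at$residue_id %in% ids)
    }
    if (t == "name") {
      nm <- advance()
      if (is.na(nm)) selectionError("'name' needs an atom name")
      hit <- if (grepl("[*?]", nm)) grepl(utils::glob2rx(nm), at$name)
             else at$name == nm
      if (!any(hit)) selectionError("atom name '%s' matches no atom", nm)
      return(hit)
    }
    selectionError("unknown selection token '%s'", t)
  }
  parse_factor <- function() {
    if (identical(peek(), "not")) { advance(); return(!parse_factor()) }
    parse_primitive()
  }
  parse_term <- function() {
    v <- parse_factor()
    while (identical(peek(), "and")) { advance(); v <- v & parse_factor() }
    v
  }
  parse_expr <- function() {
    v <- parse_term()
    while (identical(peek(), "or")) { advance(); v <- v | parse_term() }
    v
  }
  mask <- parse_expr()
  if (pos <= length(toks))
    selectionError("trailing tokens in selection: '%s'",
                   paste(toks[pos:length(toks)], collapse = " "))
  ids <- sort(at$atom_id[mask])
  if (!length(ids) && !allowEmpty)
    selectionError("selection '%s' resolved to zero atoms", expression)
  ids
}
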