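# HGVS c./g. descriptions -- the subset of the nomenclature used for USH2A
# variant reporting: substitutions, deletions, duplications, insertions,
# deletion-insertions (including delins with an inverted genomic segment),
# inversions, positions with intronic offsets and 5'/3' UTR anchors, and
# compound allele descriptions "c.[A(;)B]".

POS_RE <- "(\\*?-?[0-9]+)([+-][0-9]+)?"

parse_pos <- function(txt) {
  m <- regmatches(txt, regexec(paste0("^", POS_RE, "$"), txt))[[1]]
  if (length(m) == 0) stop("malformed HGVS position: '", txt, "'")
  base_txt <- m[2]
  star <- startsWith(base_txt, "*")
  base <- as.integer(sub("^\\*", "", base_txt))
  offset <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  list(base = base, offset = offset, star = star)
}

format_pos <- function(p) {
  paste0(if (p$star) "*" else "", p$base,
         if (p$offset != 0L) sprintf("%+d", p$offset) else "")
}

new_hgvs <- function(reference, kind, pos1, pos2 = NULL, ref = NULL, alt = NULL,
                     ins_seq = NULL, inv_range = NULL, components = NULL,
                     sep = NULL) {
  structure(list(reference = reference, kind = kind, pos1 = pos1, pos2 = pos2,
                 ref = ref, alt = alt, ins_seq = ins_seq,
                 inv_range = inv_range, components = components, sep = sep),
            class = "hgvs_variant")
}

#' Parse an HGVS c. or g. description
#'
#' Covers the constructs used in USH2A variant reporting: substitutions
#' (`c.4397-3890A>G`), deletions/duplications with one or two anchors
#' (`c.2299del`, `c.4627+25436_4987+659del`), insertions, delins with a
#' literal inserted sequence (`c.9335_9371+8063delinsGAAGACACTCC`) or an
#' inverted genomic segment (`g.42320825_215677220delins42320846_215677215inv`),
#' inversions, intronic offsets, 5' UTR (negative) and 3' UTR (`*`) anchors,
#' and compound allele descriptions `c.[A(;)B]` / `c.[A;B]`. A substitution
#' with identical reference and alternate alleles is accepted and flagged as
#' no-change. Serialising the result with [format_hgvs()] reproduces the input
#' after whitespace normalisation.
#'
#' @param description character HGVS string beginning `"c."` or `"g."`.
#' @return an object of class `hgvs_variant` with fields `reference`
#'   (`"c"`/`"g"`), `kind` (`substitution`, `deletion`, `duplication`,
#'   `insertion`, `delins`, `inversion`, `compound`), `pos1`/`pos2` anchors
#'   (`base`, `offset`, `star`), alleles, and for compounds a `components`
#'   list.
#' @examples
#' parse_hgvs("c.2299del")
#' parse_hgvs("c.4397-3890A>G")
#' @export
parse_hgvs <- function(description) {
  x <- gsub("[[:space:]]+", "", description)
  m <- regmatches(x, regexec("^([cg])\\.(.+)$", x))[[1]]
  if (length(m) == 0)
    stop("malformed HGVS description (must begin 'c.' or 'g.'): '", description, "'")
  reference <- m[2]
  body <- m[3]

  cm <- regmatches(body, regexec("^\\[(.+)\\]$", body))[[1]]
  if (length(cm) > 0) {
    inner <- cm[2]
    sep <- if (grepl("(;)", inner, fixed = TRUE)) "(;)" else ";"
    parts <- strsplit(inner, sep, fixed = TRUE)[[1]]
    comps <- lapply(parts, function(p) parse_hgvs(paste0(reference, ".", p)))
    return(new_hgvs(reference, "compound", pos1 = NULL,
                    components = comps, sep = sep))
  }

  one_two <- paste0("^", POS_RE, "(?:_", POS_RE, ")?")
  try_match <- function(suffix_re) {
    mm <- regmatches(body, regexec(paste0(one_two, suffix_re, "$"), body,
                                   perl = TRUE))[[1]]
    if (length(mm) == 0) return(NULL)
    mm
  }
  mk_pos <- function(mm, i)  # anchors sit at groups 2:3 and 4:5
    list(base = {
      b <- mm[i]
      as.integer(sub("^\\*", "", b))
    }, offset = if (nzchar(mm[i + 1])) as.integer(mm[i + 1]) else 0L,
    star = startsWith(mm[i], "*"))
  maybe_pos2 <- function(mm) if (nzchar(mm[4])) mk_pos(mm, 4) else NULL

  mm <- try_match("delins([0-9]+)_([0-9]+)inv")
  if (!is.null(mm))
    return(new_hgvs(reference, "delins", mk_pos(mm, 2), maybe_pos2(mm),
                    inv_range = c(as.integer(mm[6]), as.integer(mm[7]))))
  mm <- try_match("delins([ACGT]+)")
  if (!is.null(mm))
    return(new_hgvs(reference, "delins", mk_pos(mm, 2), maybe_pos2(mm),
                    ins_seq = mm[6]))
  mm <- try_match("del([ACGT]*)")
  if (!is.null(mm))
    return(new_hgvs(reference, "deletion", mk_pos(mm, 2), maybe_pos2(mm),
                    ref = if (nzchar(mm[6])) mm[6] else NULL))
  mm <- try_match("dup([ACGT]*)")
  if (!is.null(mm))
    return(new_hgvs(reference, "duplication", mk_pos(mm, 2), maybe_pos2(mm),
                    ref = if (nzchar(mm[6])) mm[6] else NULL))
  mm <- try_match("ins([ACGT]+)")
  if (!is.null(mm))
    return(new_hgvs(reference, "insertion", mk_pos(mm, 2), maybe_pos2(mm),
                    ins_seq = mm[6]))
  mm <- try_match("inv")
  if (!is.null(mm))
    return(new_hgvs(reference, "inversion", mk_pos(mm, 2), maybe_pos2(mm)))
  mm <- try_match("([ACGT])>([ACGT])")
  if (!is.null(mm)) {
    if (nzchar(mm[4])) stop("substitution with a position range: '", description, "'")
    v <- new_hgvs(reference, "substitution", mk_pos(mm, 2),
                  ref = mm[6], alt = mm[7])
    v$no_change <- identical(mm[6], mm[7])
    return(v)
  }
  stop("malformed HGVS description, cannot parse '", body, "' in '",
       description, "'")
}

#' Serialise an `hgvs_variant` back to its string form
#'
#' @param v an `hgvs_variant` from [parse_hgvs()].
#' @return character HGVS description; round-trips with [parse_hgvs()].
#' @export
format_hgvs <- function(v) {
  stopifnot(inherits(v, "hgvs_variant"))
  if (v$kind == "compound") {
    inner <- vapply(v$components, function(c)
      sub("^[cg]\\.", "", format_hgvs(c)), "")
    return(paste0(v$reference, ".[", paste(inner, collapse = v$sep), "]"))
  }
  anchors <- format_pos(v$pos1)
  if (!is.null(v$pos2)) anchors <- paste0(anchors, "_", format_pos(v$pos2))
  suffix <- switch(v$kind,
    substitution = paste0(v$ref, ">", v$alt),
    deletion = paste0("del", v$ref %||% ""),
    duplication = paste0("dup", v$ref %||% ""),
    insertion = paste0("ins", v$ins_seq),
    delins = if (!is.null(v$inv_range))
      paste0("delins", v$inv_range[1], "_", v$inv_range[2], "inv")
    else paste0("delins", v$ins_seq),
    inversion = "inv",
    stop("unknown kind ", v$kind))
  paste0(v$reference, ".", anchors, suffix)
}

#' @export
print.hgvs_variant <- function(x, ...) {
  cat(format_hgvs(x), sprintf(" [%s]\n", x$kind))
  invisible(x)
}

# Naive nucleotide span between the two anchors of a ranged description,
# treating intronic offsets as additive; |span| is a lower bound on the true
# genomic extent and separates small indels from structural variants.
hgvs_span <- function(v) {
  if (v$kind == "compound") return(max(vapply(v$components, hgvs_span, 1)))
  flat <- function(p) p$base + p$offset
  if (is.null(v$pos2)) return(1L)
  abs(flat(v$pos2) - flat(v$pos1)) + 1L
}

#' Is a parsed variant structural?
#'
#' Structural variants are taken as events spanning at least `min_size`
#' nucleotides (deletions, duplications, delins) or any inversion; the span is
#' measured naively between the two HGVS anchors including intronic offsets.
#'
#' @param v an `hgvs_variant`.
#' @param min_size minimum nucleotide span (default 50, the conventional SV
#'   size cutoff).
#' @return logical.
#' @export
is_structural <- function(v, min_size = 50L) {
  if (v$kind == "compound") return(any(vapply(v$components, is_structural,
                                              TRUE, min_size = min_size)))
  if (v$kind == "inversion" || !is.null(v$inv_range)) return(TRUE)
  if (!v$kind %in% c("deletion", "duplication", "delins", "insertion"))
    return(FALSE)
  hgvs_span(v) >= min_size
}

#' Structural-variant type from an HGVS description
#'
#' Total mapping used for SV accounting: `del` -> deletion, `dup` ->
#' duplication, `inv` -> inversion; a delins whose inserted material is an
#' inverted genomic segment counts as an inversion, any other delins counts
#' with the deletions. Unknown kinds map to `"other"`.
#'
#' @param v an `hgvs_variant` or a character HGVS description.
#' @return one of `"deletion"`, `"duplication"`, `"inversion"`,
#'   `"insertion"`, `"other"`.
#' @export
sv_type_from_hgvs <- function(v) {
  if (is.character(v)) v <- parse_hgvs(v)
  switch(v$kind,
    inversion = "inversion",
    delins = if (!is.null(v$inv_range)) "inversion" else "deletion",
    deletion = "deletion",
    duplication = "duplication",
    insertion = "insertion",
    "other")
}
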