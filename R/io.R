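.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a signaling edge list (SIF-compatible three-column dialect)
#'
#' Each row is `source<TAB>sign<TAB>target` with sign `+`/`activates` for
#' activation and `-`/`inhibits` for inhibition.  Lines starting with `#` are
#' ignored.  Edge ids are assigned as `e<row-index>` in file order.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `id`, `source`, `target`, `sign`,
#'   `removable` (all `TRUE`; redox-hub edges are made non-removable at
#'   assembly).
#' @export
readSignalingEdges <- function(path) {
  dat <- .read_tsv_lines(path)
  if (!length(dat$lines))
    return(data.frame(id = character(), source = character(),
                      target = character(), sign = character(),
                      removable = logical()))
  parts <- strsplit(dat$lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) != 3L || any(!nzchar(p)))
      stop("malformed edge row at line ", dat$lineno[i],
           ": expected source<TAB>sign<TAB>target", call. = FALSE)
    sign <- switch(p[2],
                   "+" = , "activates" = "activation",
                   "-" = , "inhibits" = "inhibition",
                   stop("unknown sign token '", p[2], "' at line ",
                        dat$lineno[i], call. = FALSE))
    out[[i]] <- data.frame(id = paste0("e", i), source = p[1],
                           target = p[3], sign = sign, removable = TRUE)
  }
  do.call(rbind, out)
}

#' Write a signaling edge list
#'
#' Inverse of [readSignalingEdges()] (the `removable` flag is not part of the
#' three-column dialect and is re-derived at assembly).
#' @param edges edge data.frame.
#' @param path output path.
#' @export
writeSignalingEdges <- function(edges, path) {
  sgn <- ifelse(edges$sign == "activation", "+", "-")
  writeLines(paste(edges$source, sgn, edges$target, sep = "\t"), path)
  invisible(path)
}

.parse_equation <- function(eq, rid, lineno = NA) {
  where <- if (is.na(lineno)) paste0("reaction ", rid)
           else paste0("line ", lineno, " (", rid, ")")
  rev <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (rev) "<=>" else "->"
  if (!rev && !grepl("->", eq, fixed = TRUE))
    stop("no reaction arrow in ", where, call. = FALSE)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2) stop("multiple arrows in ", where, call. = FALSE)
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s, sgn) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    coefs <- numeric(); nms <- character()
    for (tm in terms) {
      if (!nzchar(tm)) stop("unbalanced token in ", where, call. = FALSE)
      toks <- strsplit(tm, "\\s+")[[1]]
      if (length(toks) == 1) { cf <- 1; met <- toks }
      else if (length(toks) == 2 &&
               !is.na(suppressWarnings(as.numeric(toks[1])))) {
        cf <- as.numeric(toks[1]); met <- toks[2]
      } else stop("unbalanced token '", tm, "' in ", where, call. = FALSE)
      coefs <- c(coefs, sgn * cf); nms <- c(nms, met)
    }
    setNames(coefs, nms)
  }
  st <- c(parse_side(sides[1], -1), parse_side(sides[2], +1))
  # merge duplicate mentions (e.g. a metabolite on both sides)
  st <- tapply(st, names(st), sum)
  st <- setNames(as.numeric(st), names(st))
  st <- st[st != 0]
  list(stoich = st, reversible = rev,
       exchange = !nzchar(trimws(sides[1])) || !nzchar(trimws(sides[2])))
}

#' Read a metabolic reaction table
#'
#' Five tab-separated columns: reaction id, equation (`a + 2 b -> c` or
#' `a <=> b`; one empty side marks an exchange reaction), standard transformed
#' Gibbs energy in kJ/mol (empty = unknown), catalyzing enzyme id (empty =
#' none), flux capacity (empty = 1000).  Metabolites are registered on first
#' mention.
#'
#' @param path path to the TSV file.
#' @return list with `reactions` (data.frame), `stoichiometry` (named list)
#'   and `metabolites` (data.frame, `boundary` not yet assigned).
#' @export
readReactionTable <- function(path) {
  dat <- .read_tsv_lines(path)
  rx <- data.frame(id = character(), reversible = logical(),
                   delta_g = numeric(), enzyme = character(),
                   flux_bound = numeric(), exchange = logical())
  stoich <- list()
  for (i in seq_along(dat$lines)) {
    p <- strsplit(dat$lines[i], "\t", fixed = TRUE)[[1]]
    length(p) <- 5L
    p[is.na(p)] <- ""
    p <- trimws(p)
    if (!nzchar(p[1]) || !nzchar(p[2]))
      stop("malformed reaction row at line ", dat$lineno[i], call. = FALSE)
    if (p[1] %in% rx$id)
      stop("duplicate reaction id '", p[1], "' at line ", dat$lineno[i],
           call. = FALSE)
    dg <- if (nzchar(p[3])) suppressWarnings(as.numeric(p[3])) else NA_real_
    if (nzchar(p[3]) && is.na(dg))
      stop("non-numeric delta_g '", p[3], "' at line ", dat$lineno[i],
           call. = FALSE)
    ub <- if (nzchar(p[5])) suppressWarnings(as.numeric(p[5])) else 1000
    if (is.na(ub) || ub <= 0)
      stop("invalid flux_bound at line ", dat$lineno[i], call. = FALSE)
    eqn <- .parse_equation(p[2], p[1], dat$lineno[i])
    rx <- rbind(rx, data.frame(
      id = p[1], reversible = eqn$reversible, delta_g = dg,
      enzyme = if (nzchar(p[4])) p[4] else NA_character_,
      flux_bound = ub, exchange = eqn$exchange))
    stoich[[p[1]]] <- eqn$stoich
  }
  mets <- unique(unlist(lapply(stoich, names)))
  list(reactions = rx, stoichiometry = stoich,
       metabolites = data.frame(id = mets, name = mets, boundary = NA))
}

.format_equation <- function(st, reversible) {
  side <- function(v) paste(ifelse(v == 1, names(v),
                                   paste(format(v, trim = TRUE), names(v))),
                            collapse = " + ")
  subs <- -st[st < 0]; prods <- st[st > 0]
  paste(if (length(subs)) side(subs) else "",
        if (reversible) "<=>" else "->",
        if (length(prods)) side(prods) else "")
}

#' Write a metabolic reaction table
#' @param reactions reaction data.frame (as in [IntegratedNetwork-class]).
#' @param stoichiometry named list of named numeric stoichiometries.
#' @param path output path.
#' @export
writeReactionTable <- function(reactions, stoichiometry, path) {
  rows <- vapply(seq_len(nrow(reactions)), function(i) {
    r <- reactions[i, ]
    paste(r$id,
          trimws(.format_equation(stoichiometry[[r$id]], r$reversible)),
          if (is.na(r$delta_g)) "" else format(r$delta_g, trim = TRUE),
          if (is.na(r$enzyme)) "" else r$enzyme,
          format(r$flux_bound, trim = TRUE),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read a measurement table
#'
#' Four tab-separated columns: id, fold-change ratio (resistant/sensitive),
#' significance flag (0/1), layer (`protein` or `metabolite`).
#'
#' @param path path to the TSV file.
#' @return a [MeasurementSet-class].  Unknown ids are rejected later, at
#'   network assembly.
#' @export
readMeasurements <- function(path) {
  dat <- .read_tsv_lines(path)
  pr <- mt <- data.frame(id = character(), ratio = numeric(),
                         significant = logical())
  for (i in seq_along(dat$lines)) {
    p <- trimws(strsplit(dat$lines[i], "\t", fixed = TRUE)[[1]])
    if (length(p) != 4L)
      stop("malformed measurement row at line ", dat$lineno[i], call. = FALSE)
    ratio <- suppressWarnings(as.numeric(p[2]))
    if (is.na(ratio) || ratio <= 0)
      stop("ratio must be a positive number at line ", dat$lineno[i],
           call. = FALSE)
    row <- data.frame(id = p[1], ratio = ratio, significant = p[3] == "1")
    if (p[4] == "protein") pr <- rbind(pr, row)
    else if (p[4] == "metabolite") mt <- rbind(mt, row)
    else stop("unknown layer '", p[4], "' at line ", dat$lineno[i],
              call. = FALSE)
  }
  new("MeasurementSet", proteins = pr, metabolites = mt)
}

#' Write a measurement table
#' @param measurements a [MeasurementSet-class].
#' @param path output path.
#' @export
writeMeasurements <- function(measurements, path) {
  fmt <- function(df, layer)
    if (nrow(df)) paste(df$id, format(df$ratio, trim = TRUE, digits = 15),
                        as.integer(df$significant), layer, sep = "\t")
    else character()
  writeLines(c(fmt(proteinRatios(measurements), "protein"),
               fmt(metaboliteRatios(measurements), "metabolite")), path)
  invisible(path)
}

#' Serialize a network to canonical JSON
#'
#' One document with keys `nodes`, `edges`, `metabolites`, `reactions`; all
#' arrays sorted by id so equal networks serialize identically.
#'
#' @param network an [IntegratedNetwork-class].
#' @param path output path.
#' @export
writeNetworkJSON <- function(network, path) {
  srt <- function(df) df[order(df$id), , drop = FALSE]
  rx <- srt(network@reactions)
  rx_list <- lapply(seq_len(nrow(rx)), function(i) {
    st <- network@stoichiometry[[rx$id[i]]]
    st <- st[order(names(st))]
    c(as.list(rx[i, c("id", "reversible", "delta_g", "enzyme",
                      "flux_bound", "exchange")]),
      list(stoichiometry = as.list(st)))
  })
  doc <- list(nodes = srt(network@nodes), edges = srt(network@edges),
              metabolites = srt(network@metabolites), reactions = rx_list,
              standalone_enzymes = sort(network@standaloneEnzymes),
              interface = sort(network@interface))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a network from its canonical JSON serialization
#' @param path path written by [writeNetworkJSON()].
#' @return an [IntegratedNetwork-class].
#' @export
readNetworkJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  rx_raw <- doc$reactions
  if (is.data.frame(rx_raw))  # uniform rows simplify to a data.frame
    rx_raw <- lapply(seq_len(nrow(rx_raw)), function(i) {
      r <- as.list(rx_raw[i, , drop = FALSE])
      # stoichiometry simplifies to a nested data.frame column; keep the
      # whole 1-row slice so unlist() below recovers all coefficients
      r$stoichiometry <- rx_raw$stoichiometry[i, , drop = FALSE]
      if (!is.null(r$delta_g) && is.na(r$delta_g)) r$delta_g <- NULL
      if (!is.null(r$enzyme) && is.na(r$enzyme)) r$enzyme <- NULL
      r
    })
  stoich <- list()
  rx <- data.frame(id = character(), reversible = logical(),
                   delta_g = numeric(), enzyme = character(),
                   flux_bound = numeric(), exchange = logical())
  for (r in rx_raw) {
    st <- unlist(r$stoichiometry)
    stoich[[r$id]] <- st[!is.na(st)]  # data.frame simplification pads NAs
    rx <- rbind(rx, data.frame(
      id = r$id, reversible = r$reversible,
      delta_g = if (is.null(r$delta_g)) NA_real_ else r$delta_g,
      enzyme = if (is.null(r$enzyme)) NA_character_ else r$enzyme,
      flux_bound = r$flux_bound, exchange = r$exchange))
  }
  fix <- function(df, cols) {
    if (is.null(df) || !NROW(df)) {
      df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
    }
    df
  }
  nodes <- fix(doc$nodes, c("id", "name", "kind", "redox_effect"))
  if (nrow(nodes) && !is.null(nodes$redox_effect))
    nodes$redox_effect[is.na(nodes$redox_effect)] <- "none"
  new("IntegratedNetwork",
      nodes = nodes,
      edges = fix(doc$edges, c("id", "source", "target", "sign", "removable")),
      metabolites = fix(doc$metabolites, c("id", "name", "boundary")),
      reactions = rx, stoichiometry = stoich,
      standaloneEnzymes = as.character(doc$standalone_enzymes),
      interface = as.character(doc$interface))
}
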