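.export_check <- function(problem) {
  if (length(problem@bilinear))
    stop("problem contains bilinear rows, which LP/MPS formats cannot ",
         "carry; call linearize() first", call. = FALSE)
}

.lp_terms <- function(coef) {
  paste(vapply(seq_along(coef), function(k) {
    v <- coef[[k]]
    sprintf("%s %.15g %s", if (k == 1 && v >= 0) "" else if (v >= 0) "+"
            else "-", abs(v), names(coef)[k])
  }, character(1)), collapse = " ")
}

#' Export a problem in CPLEX LP format
#'
#' Variable order is the sorted registry, so files are stable across runs.
#'
#' @param problem a [MipProblem-class] in big-M encoding.
#' @param path output path.
#' @export
exportLP <- function(problem, path) {
  .export_check(problem)
  vars <- problem@variables[order(problem@variables$name), , drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  writeLines("Minimize", con)
  obj <- problem@objective[sort(names(problem@objective))]
  writeLines(paste(" obj:", if (length(obj)) .lp_terms(obj) else "0 dummy"),
             con)
  writeLines("Subject To", con)
  for (k in seq_along(problem@linear)) {
    r <- problem@linear[[k]]
    rel <- switch(r$rel, "<=" = "<=", ">=" = ">=", "=" = "=")
    nm <- if (nzchar(r$name)) r$name else paste0("c", k)
    writeLines(sprintf(" %s: %s %s %.15g", nm, .lp_terms(r$coef), rel,
                       r$rhs), con)
  }
  writeLines("Bounds", con)
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    if (v$lb == v$ub) writeLines(sprintf(" %s = %.15g", v$name, v$lb), con)
    else writeLines(sprintf(" %s <= %s <= %s",
                            if (is.finite(v$lb)) sprintf("%.15g", v$lb)
                            else "-inf",
                            v$name,
                            if (is.finite(v$ub)) sprintf("%.15g", v$ub)
                            else "+inf"), con)
  }
  bins <- vars$name[vars$kind == "binary"]
  if (length(bins)) {
    writeLines("Binaries", con)
    writeLines(paste("", paste(bins, collapse = " ")), con)
  }
  if (!length(obj)) writeLines("General", con)  # keeps 'dummy' harmless
  writeLines("End", con)
  invisible(path)
}

#' Export a problem in MPS format
#'
#' @inheritParams exportLP
#' @export
exportMPS <- function(problem, path) {
  .export_check(problem)
  vars <- problem@variables[order(problem@variables$name), , drop = FALSE]
  rows <- problem@linear
  rnames <- vapply(seq_along(rows), function(k)
    if (nzchar(rows[[k]]$name)) rows[[k]]$name else paste0("c", k),
    character(1))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("NAME          REDOXMIP", con)
  writeLines("ROWS", con)
  writeLines(" N  COST", con)
  for (k in seq_along(rows))
    writeLines(sprintf(" %s  %s",
                       switch(rows[[k]]$rel, "<=" = "L", ">=" = "G",
                              "=" = "E"), rnames[k]), con)
  writeLines("COLUMNS", con)
  by_var <- lapply(setNames(vars$name, vars$name), function(nm) {
    ent <- list()
    if (nm %in% names(problem@objective))
      ent[["COST"]] <- problem@objective[[nm]]
    for (k in seq_along(rows))
      if (nm %in% names(rows[[k]]$coef))
        ent[[rnames[k]]] <- rows[[k]]$coef[[nm]]
    ent
  })
  in_int <- FALSE
  marker <- function(kind)
    writeLines(sprintf("    MARKER    'MARKER'    '%s'", kind), con)
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    isbin <- v$kind == "binary"
    if (isbin && !in_int) { marker("INTORG"); in_int <- TRUE }
    if (!isbin && in_int) { marker("INTEND"); in_int <- FALSE }
    for (rn in names(by_var[[v$name]]))
      writeLines(sprintf("    %-10s %-10s %.15g", v$name, rn,
                         by_var[[v$name]][[rn]]), con)
  }
  if (in_int) marker("INTEND")
  writeLines("RHS", con)
  for (k in seq_along(rows))
    if (rows[[k]]$rhs != 0)
      writeLines(sprintf("    RHS       %-10s %.15g", rnames[k],
                         rows[[k]]$rhs), con)
  writeLines("BOUNDS", con)
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    if (v$lb == v$ub)
      writeLines(sprintf(" FX BND       %-10s %.15g", v$name, v$lb), con)
    else if (v$kind == "binary" && v$lb == 0 && v$ub == 1)
      writeLines(sprintf(" BV BND       %s", v$name), con)
    else {
      if (is.finite(v$lb))
        writeLines(sprintf(" LO BND       %-10s %.15g", v$name, v$lb), con)
      else writeLines(sprintf(" MI BND       %s", v$name), con)
      if (is.finite(v$ub))
        writeLines(sprintf(" UP BND       %-10s %.15g", v$name, v$ub), con)
    }
  }
  writeLines("ENDATA", con)
  invisible(path)
}

#' Re-import an LP file written by [exportLP()]
#'
#' Parses the subset of the CPLEX LP dialect this package writes, producing
#' a problem the solver layer can optimize; used to verify export
#' round-trips.
#'
#' @param path LP file.
#' @return a [MipProblem-class] (without network bookkeeping).
#' @export
readLP <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sec <- "none"
  obj <- numeric(); rows <- list()
  bounds <- list(); bins <- character()
  parse_terms <- function(s) {
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    coef <- numeric(); sign <- 1; pend <- NA_real_
    for (tk in toks) {
      if (tk == "+") { sign <- 1 }
      else if (tk == "-") { sign <- -1 }
      else if (grepl("^[-+]?[0-9.eE+-]+$", tk) &&
               !is.na(suppressWarnings(as.numeric(tk)))) {
        pend <- sign * as.numeric(tk); sign <- 1
      } else {
        coef[tk] <- (if (tk %in% names(coef)) coef[[tk]] else 0) +
          (if (is.na(pend)) sign else pend)
        pend <- NA_real_; sign <- 1
      }
    }
    coef
  }
  for (ln in lines) {
    t <- trimws(ln)
    low <- tolower(t)
    if (low %in% c("minimize", "maximize")) { sec <- "obj"; next }
    if (low == "subject to") { sec <- "st"; next }
    if (low == "bounds") { sec <- "bounds"; next }
    if (low %in% c("binaries", "binary")) { sec <- "bin"; next }
    if (low %in% c("general", "end")) { sec <- "none"; next }
    if (sec == "obj") {
      t <- sub("^[^:]*:", "", t)
      o <- parse_terms(t)
      for (nm in names(o)) obj[nm] <- (if (nm %in% names(obj)) obj[[nm]]
                                       else 0) + o[[nm]]
    } else if (sec == "st") {
      body <- sub("^[^:]*:", "", t)
      m <- regmatches(body, regexec("^(.*?)(<=|>=|=)\\s*([-+0-9.eE]+)\\s*$",
                                    body))[[1]]
      if (length(m) != 4) stop("cannot parse constraint: ", t, call. = FALSE)
      rows[[length(rows) + 1L]] <- list(coef = parse_terms(m[2]),
                                        rel = m[3],
                                        rhs = as.numeric(m[4]), name = "")
    } else if (sec == "bounds") {
      if (grepl("<=.*<=", t)) {
        p <- strsplit(t, "<=")[[1]]
        nm <- trimws(p[2])
        lo <- trimws(p[1]); hi <- trimws(p[3])
        bounds[[nm]] <- c(if (lo == "-inf") -Inf else as.numeric(lo),
                          if (hi == "+inf") Inf else as.numeric(hi))
      } else if (grepl("=", t, fixed = TRUE)) {
        p <- strsplit(t, "=", fixed = TRUE)[[1]]
        bounds[[trimws(p[1])]] <- rep(as.numeric(trimws(p[2])), 2)
      }
    } else if (sec == "bin") {
      bins <- c(bins, strsplit(t, "\\s+")[[1]])
    }
  }
  obj <- obj[names(obj) != "dummy"]
  nms <- sort(unique(c(names(obj), unlist(lapply(rows, function(r)
    names(r$coef))), names(bounds), bins)))
  nms <- setdiff(nms, "dummy")
  vars <- do.call(rbind, lapply(nms, function(nm) {
    b <- bounds[[nm]]
    isbin <- nm %in% bins
    if (is.null(b)) b <- if (isbin) c(0, 1) else c(0, Inf)
    data.frame(name = nm, kind = if (isbin) "binary" else "continuous",
               lb = b[1], ub = b[2])
  }))
  rows <- lapply(rows, function(r) {
    r$coef <- r$coef[names(r$coef) %in% nms]
    r
  })
  finite_ub <- vars$ub[vars$kind == "continuous" & is.finite(vars$ub)]
  new("MipProblem", variables = vars, linear = rows, bilinear = list(),
      objective = obj, weights = c(w1 = 1, w2 = 1, w3 = 0.01),
      bigM = max(2, 2 * c(finite_ub, 1)), encoding = "big-M",
      varMap = list(), options = mipOptions())
}

#' Read a configuration file (YAML or JSON)
#'
#' Recognized keys: `weights` (w1, w2, w3), `fold_threshold`, `tau`, `c_lo`,
#' `c_hi`, `big_m`, `encoding`, `propagate`, `seed`, `time_limit`.
#'
#' @param path config file; `.yaml`/`.yml` parsed with yaml, otherwise JSON.
#' @return list with `weights`, `options` (for [buildProblem()]), `seed`,
#'   `time_limit`.
#' @export
readConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  opt_keys <- intersect(names(cfg), names(mipOptions()))
  list(weights = if (!is.null(cfg$weights)) unlist(cfg$weights)
                 else c(1, 1, 0.01),
       options = modifyList(mipOptions(), cfg[opt_keys]),
       seed = if (!is.null(cfg$seed)) cfg$seed else 1L,
       time_limit = cfg$time_limit)
}
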