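#' Export a rule base as human-readable text
#'
#' One line per rule in the `IF (var IS term) AND ... THEN (target = ...)`
#' format used when reporting Takagi-Sugeno tremor models. Don't-care clauses
#' are rendered as `IS any value`.
#'
#' @param model A [ts_model()].
#' @param digits Significant digits for the printed coefficients.
#' @return Character vector, one element per rule.
#' @export
export_rules <- function(model, digits = 6) {
  stopifnot(inherits(model, "ts_model"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  vapply(seq_along(model$rules), function(j) {
    r <- model$rules[[j]]
    clauses <- vapply(model$variables, function(v) {
      s <- r$sets[[v]]
      sprintf("(%s IS %s)", v,
              if (is.null(s)) "any value"
              else if (nzchar(s$label)) s$label else "term")
    }, character(1))
    terms <- character(0)
    for (v in model$variables) {
      a <- r$coefficients[[v]]
      op <- if (length(terms) == 0L) {
        if (a < 0) "-" else ""
      } else if (a < 0) " - " else " + "
      terms <- c(terms, sprintf("%s%s * %s", op, fmt(abs(a)), v))
    }
    b <- r$intercept
    terms <- c(terms, sprintf("%s%s", if (b < 0) " - " else " + ", fmt(abs(b))))
    sprintf("RULE %d: IF %s THEN (%s = %s)", j,
            paste(clauses, collapse = " AND "), model$target,
            paste(terms, collapse = ""))
  }, character(1))
}

# Default placement of labelled placeholder sets on a universe: linguistic
# ranks low < medium < high; unknown labels sit at the center.
.label_position <- function(label, universe) {
  pos <- switch(tolower(label), low = 0.25, medium = 0.5, high = 0.75, 0.5)
  universe[1] + pos * diff(universe)
}

#' Parse a textual rule base into a Takagi-Sugeno model
#'
#' Inverse of [export_rules()]: reads `RULE k: IF ... THEN (...)` lines.
#' Printed rule bases carry only the linguistic labels of the antecedent sets,
#' not their Gaussian parameters, so unless `sets` supplies them each labelled
#' clause gets a placeholder set (label-ranked center, spread `default_sigma`);
#' replace them with [set_rule_antecedent()] when exact memberships matter.
#' Variables appearing in consequents but not in a rule's antecedent are
#' treated as don't-care clauses.
#'
#' @param text Character vector of rule lines (blank lines and `#` comments are
#'   skipped), or a single file path.
#' @param sets Optional nested named list `sets[[variable]][[label]]` of
#'   [gaussian_set()] objects to attach to the clauses.
#' @param universe Shared universe of discourse for placeholder sets.
#' @param default_sigma Spread of placeholder sets.
#' @return A [ts_model()].
#' @export
parse_rules <- function(text, sets = NULL, universe = c(0, 1),
                        default_sigma = 0.15) {
  if (length(text) == 1L && !grepl("RULE", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  text <- trimws(text)
  text <- text[nzchar(text) & !startsWith(text, "#")]
  if (!length(text)) stop("no rule lines found", call. = FALSE)

  m <- regexec("^RULE\\s+(\\d+)\\s*:\\s*IF\\s+(.*)\\s+THEN\\s*\\((.*)\\)\\s*$",
               text)
  parts <- regmatches(text, m)
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad))
    stop("line ", bad[1], " is not a well-formed rule: ", text[bad[1]],
         call. = FALSE)

  parsed <- lapply(parts, function(p) {
    ante <- p[3]
    cl <- regmatches(ante,
      gregexpr("\\(\\s*([^()]+?)\\s+IS\\s+([^()]+?)\\s*\\)", ante))[[1]]
    clauses <- lapply(cl, function(s) {
      mm <- regexec("\\(\\s*([^()]+?)\\s+IS\\s+([^()]+?)\\s*\\)", s)[[1]]
      c(variable = substr(s, mm[2], mm[2] + attr(mm, "match.length")[2] - 1L),
        label = substr(s, mm[3], mm[3] + attr(mm, "match.length")[3] - 1L))
    })
    cons <- p[4]
    eq <- regexec("^\\s*(\\S+)\\s*=\\s*(.*)$", cons)[[1]]
    if (length(eq) != 3L) stop("malformed consequent: ", cons, call. = FALSE)
    target <- regmatches(cons, list(eq))[[1]][2]
    expr <- regmatches(cons, list(eq))[[1]][3]
    # split into signed terms: [sign] number [* variable]
    tm <- gregexpr(paste0("[+-]?\\s*[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                          "(\\s*\\*\\s*[A-Za-z_.][A-Za-z0-9_.]*)?"), expr)
    toks <- trimws(regmatches(expr, tm)[[1]])
    coefs <- numeric(0); intercept <- 0
    for (tk in toks) {
      sign <- if (startsWith(tk, "-")) -1 else 1
      tk2 <- sub("^[+-]\\s*", "", tk)
      if (grepl("\\*", tk2)) {
        bits <- strsplit(tk2, "\\s*\\*\\s*")[[1]]
        coefs[bits[2]] <- sign * as.numeric(bits[1])
      } else {
        intercept <- sign * as.numeric(tk2)
      }
    }
    list(clauses = clauses, target = target, coefs = coefs,
         intercept = intercept)
  })

  variables <- unique(unlist(lapply(parsed, function(p) names(p$coefs))))
  if (!length(variables)) stop("no consequent variables found", call. = FALSE)
  target <- parsed[[1]]$target
  if (!is.list(universe))
    uni <- stats::setNames(rep(list(universe), length(variables)), variables)
  else uni <- universe

  rules <- lapply(parsed, function(p) {
    rsets <- stats::setNames(vector("list", length(variables)), variables)
    for (cl in p$clauses) {
      v <- cl[["variable"]]; lab <- cl[["label"]]
      if (!v %in% variables)
        stop("antecedent variable '", v, "' never appears in a consequent",
             call. = FALSE)
      if (tolower(lab) == "any value") next
      s <- if (!is.null(sets)) sets[[v]][[lab]] else NULL
      if (is.null(s))
        s <- gaussian_set(.label_position(lab, uni[[v]]), default_sigma, lab)
      rsets[v] <- list(s)
    }
    co <- stats::setNames(numeric(length(variables)), variables)
    co[names(p$coefs)] <- p$coefs
    ts_rule(rsets, co, p$intercept)
  })
  ts_model(variables, rules, universe = uni, target = target)
}

#' Read/write a Takagi-Sugeno model as JSON
#'
#' The JSON file records the variable ordering, the per-rule Gaussian set
#' parameters (or don't-care), consequent coefficients, the universe of
#' discourse, and the normalization contract under which the consequents were
#' fitted, so a model file is self-contained and reproducible.
#'
#' @param model A [ts_model()].
#' @param path File path.
#' @return `read_ts_model` returns a [ts_model()]; `write_ts_model` returns
#'   `path` invisibly.
#' @export
write_ts_model <- function(model, path) {
  stopifnot(inherits(model, "ts_model"))
  obj <- list(
    variables = model$variables,
    target = model$target,
    universe = model$universe,
    rules = lapply(model$rules, function(r) list(
      sets = lapply(r$sets, function(s)
        if (is.null(s)) NULL else list(mu = s$mu, sigma = s$sigma,
                                       label = s$label)),
      coefficients = as.list(r$coefficients),
      intercept = r$intercept)),
    normalization = model$normalization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ts_model
#' @export
read_ts_model <- function(path) {
  obj <- jsonlite::read_json(path)
  variables <- unlist(obj$variables)
  rules <- lapply(obj$rules, function(r) {
    rsets <- stats::setNames(vector("list", length(variables)), variables)
    for (v in variables) {
      s <- r$sets[[v]]
      if (!is.null(s))
        rsets[v] <- list(gaussian_set(s$mu, s$sigma, s$label %||% ""))
    }
    ts_rule(rsets, unlist(r$coefficients)[variables], r$intercept)
  })
  uni <- lapply(obj$universe, function(u) unlist(u))
  norm <- if (is.null(obj$normalization)) NULL else
    lapply(obj$normalization, function(x)
      if (is.list(x)) lapply(x, unlist) else unlist(x))
  ts_model(variables, rules, universe = uni, target = obj$target,
           normalization = norm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
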