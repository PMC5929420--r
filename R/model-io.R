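# Model construction and I/O: the tabular dialect, SBML reading, flux tables.

# Build a validated MetabolicModel from a parsed reaction table.
# `stoich` is a list (parallel to rows) of named numeric vectors.
.newModel <- function(ids, stoich, lb, ub, genes, objective,
                      metNames = NULL, metComp = NULL) {
  metIds <- unique(unlist(lapply(stoich, names), use.names = FALSE))
  if (is.null(metIds)) metIds <- character(0)
  triplets <- do.call(rbind, lapply(seq_along(stoich), function(j) {
    s <- stoich[[j]]
    if (!length(s)) return(NULL)
    cbind(i = match(names(s), metIds), j = j, x = unname(s))
  }))
  S <- Matrix::sparseMatrix(
    i = triplets[, "i"], j = triplets[, "j"], x = triplets[, "x"],
    dims = c(length(metIds), length(ids)),
    dimnames = list(metIds, ids)
  )
  nmet <- vapply(stoich, function(s) sum(s != 0), integer(1))
  mets <- data.frame(
    id = metIds,
    name = if (is.null(metNames)) metIds else metNames[metIds],
    compartment = if (is.null(metComp)) rep("c", length(metIds)) else metComp[metIds],
    stringsAsFactors = FALSE
  )
  rxns <- data.frame(
    id = ids, lower_bound = lb, upper_bound = ub,
    is_exchange = nmet == 1L, stringsAsFactors = FALSE
  )
  new("MetabolicModel", metabolites = mets, reactions = rxns,
      genes = genes, stoichiometry = S, objective = objective)
}

# Parse one equation of the tabular dialect, e.g. "1 A + 2 B -> 1 C".
# Returns list(stoich = named numeric, reversible = logical).
.parseEquation <- function(eq, where = "") {
  reversible <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "->"
  if (!grepl(arrow, eq, fixed = TRUE))
    .formatError(sprintf("malformed equation%s: no '->' or '<=>' in %s", where, dQuote(eq)))
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L)
    .formatError(sprintf("malformed equation%s: more than one arrow in %s", where, dQuote(eq)))
  parseSide <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      m <- regmatches(term, regexec(
        "^([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?[[:space:]]+)?([^[:space:]]+)$", term))[[1]]
      if (length(m) == 0L || !nzchar(m[4]))
        .formatError(sprintf("malformed term %s in equation%s", dQuote(term), where))
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      met <- m[4]
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  left <- parseSide(sides[1], -1)
  right <- parseSide(sides[2], +1)
  st <- left
  for (met in names(right))
    st[met] <- (if (met %in% names(st)) st[[met]] else 0) + right[[met]]
  st <- st[st != 0]
  if (!length(st))
    .formatError(sprintf("equation%s has empty net stoichiometry: %s", where, dQuote(eq)))
  list(stoich = st, reversible = reversible)
}

# Shared core for readTabularModel and the fixture builders: a data.frame with
# character columns reaction_id, equation, lower_bound, upper_bound, genes,
# objective (empty strings mean "use the default").
.modelFromTable <- function(df, source = "<table>") {
  need <- c("reaction_id", "equation", "lower_bound", "upper_bound", "genes", "objective")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .formatError(sprintf("%s: missing column(s) %s", source, paste(miss, collapse = ", ")))
  n <- nrow(df)
  stoich <- vector("list", n)
  lb <- ub <- numeric(n)
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    where <- sprintf(" (%s line %d)", source, i)
    pe <- .parseEquation(df$equation[i], where)
    stoich[[i]] <- pe$stoich
    dlb <- if (pe$reversible) -1000 else 0
    lbi <- trimws(df$lower_bound[i])
    ubi <- trimws(df$upper_bound[i])
    lb[i] <- if (nzchar(lbi)) suppressWarnings(as.numeric(lbi)) else dlb
    ub[i] <- if (nzchar(ubi)) suppressWarnings(as.numeric(ubi)) else 1000
    if (is.na(lb[i]) || is.na(ub[i]))
      .formatError(sprintf("non-numeric bound%s", where))
    g <- trimws(strsplit(df$genes[i], ";", fixed = TRUE)[[1]])
    genes[[i]] <- g[nzchar(g)]
  }
  objFlag <- trimws(df$objective) %in% c("1", "TRUE", "true")
  if (sum(objFlag) != 1L)
    .configError(sprintf("%s: exactly one row must carry objective = 1 (found %d)",
                         source, sum(objFlag)))
  .newModel(trimws(df$reaction_id), stoich, lb, ub, genes,
            objective = trimws(df$reaction_id)[objFlag])
}

#' Read a metabolic model from the tabular dialect
#'
#' A TSV with header columns `reaction_id`, `equation`, `lower_bound`,
#' `upper_bound`, `genes`, `objective`. Equations use `"->"` for irreversible
#' reactions (default lower bound 0) and `"<=>"` for reversible ones (default
#' lower bound -1000); the default upper bound is 1000 mmol/gDW/h and explicit
#' bounds override the defaults. `genes` is a semicolon-separated list (may be
#' empty); exactly one row must set `objective` to 1. Lines starting with `#`
#' are ignored.
#'
#' @param path path to the TSV file.
#' @return a validated [MetabolicModel-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeTabularModel(makeFixtureModel("CHAIN3"), tf)
#' m <- readTabularModel(tf)
#' objectiveId(m)
#' @export
readTabularModel <- function(path) {
  if (!file.exists(path)) .ioError(sprintf("model file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          blank.lines.skip = TRUE, quote = "")
  names(df) <- trimws(names(df))
  .modelFromTable(df, source = basename(path))
}

#' Write a metabolic model in the tabular dialect
#'
#' Inverse of [readTabularModel()]: bounds are written explicitly at full
#' precision, so the written file round-trips to an identical model.
#'
#' @param model a [MetabolicModel-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTabularModel <- function(model, path) {
  S <- stoichMatrix(model)
  eqs <- vapply(seq_len(nReactions(model)), function(j) {
    s <- S[, j]
    s <- s[s != 0]
    fmt <- function(v) paste(sprintf("%s %s", .fmtNum(abs(v)), names(v)), collapse = " + ")
    left <- s[s < 0]; right <- s[s > 0]
    arrow <- if (model@reactions$lower_bound[j] < 0) "<=>" else "->"
    paste(if (length(left)) fmt(left) else "",
          arrow,
          if (length(right)) fmt(right) else "")
  }, character(1))
  df <- data.frame(
    reaction_id = reactionIds(model),
    equation = trimws(eqs),
    lower_bound = vapply(model@reactions$lower_bound, .fmtNum, character(1)),
    upper_bound = vapply(model@reactions$upper_bound, .fmtNum, character(1)),
    genes = vapply(model@genes, paste, character(1), collapse = ";"),
    objective = as.integer(reactionIds(model) == objectiveId(model)),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .ioError(sprintf("cannot write model to %s", path))
  invisible(path)
}

# ---- SBML ------------------------------------------------------------------

.xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(at)) == name)
  if (length(hit)) at[[hit[1]]] else NA_character_
}

.xfind <- function(node, local) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", local))
}

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 3 with the `fbc` package (flux bounds as parameter
#' references, `geneProductAssociation` for gene links, `listOfObjectives` for
#' the objective) and the legacy Level 2 COBRA dialect (bounds as
#' `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters, genes in
#' `GENE_ASSOCIATION` notes). Gene associations are flattened to the plain list
#' of gene identifiers appearing in the association expression: the constraining
#' step uses only the highest-expressed associated gene, so AND/OR structure is
#' deliberately discarded. Missing bounds default to \eqn{[-1000, 1000]} for
#' reversible and \eqn{[0, 1000]} for irreversible reactions.
#'
#' @param path path to an SBML file.
#' @param objective optional reaction id to use as the objective when the file
#'   declares none (or to override the declared one).
#' @return a validated [MetabolicModel-class].
#' @export
readSBMLModel <- function(path, objective = NULL) {
  if (!file.exists(path)) .ioError(sprintf("SBML file not found: %s", path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) .formatError(sprintf("cannot parse SBML %s: %s",
                                                           basename(path), conditionMessage(e))))
  modelNode <- .xfind(doc, "model")
  if (!length(modelNode)) .formatError(sprintf("%s: no <model> element", basename(path)))
  modelNode <- modelNode[[1]]

  # global fbc/plain parameters (bound values)
  params <- .xfind(modelNode, "parameter")
  pvals <- stats::setNames(
    suppressWarnings(as.numeric(vapply(params, .xattr, character(1), "value"))),
    vapply(params, .xattr, character(1), "id"))

  # gene products: fbc id -> label (fall back to id)
  gps <- .xfind(modelNode, "geneProduct")
  gpLabel <- stats::setNames(
    ifelse(is.na(vapply(gps, .xattr, character(1), "label")),
           vapply(gps, .xattr, character(1), "id"),
           vapply(gps, .xattr, character(1), "label")),
    vapply(gps, .xattr, character(1), "id"))

  species <- .xfind(modelNode, "species")
  if (!length(species)) .formatError(sprintf("%s: no species declared", basename(path)))
  metIds <- vapply(species, .xattr, character(1), "id")
  metNames <- vapply(species, .xattr, character(1), "name")
  metNames <- stats::setNames(ifelse(is.na(metNames), metIds, metNames), metIds)
  metComp <- stats::setNames(
    ifelse(is.na(vapply(species, .xattr, character(1), "compartment")), "c",
           vapply(species, .xattr, character(1), "compartment")), metIds)
  boundary <- vapply(species, .xattr, character(1), "boundaryCondition") %in% c("true", "1")
  names(boundary) <- metIds

  rxNodes <- xml2::xml_find_all(modelNode, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rxNodes)) .formatError(sprintf("%s: no reactions declared", basename(path)))
  n <- length(rxNodes)
  ids <- character(n); stoich <- vector("list", n)
  lb <- ub <- numeric(n); genes <- vector("list", n)
  for (i in seq_len(n)) {
    rx <- rxNodes[[i]]
    ids[i] <- .xattr(rx, "id")
    if (is.na(ids[i]) || !nzchar(ids[i]))
      .formatError(sprintf("%s: reaction #%d has no id", basename(path), i))
    rev <- isTRUE(.xattr(rx, "reversible") %in% c("true", "1"))
    side <- function(tag, sign) {
      refs <- xml2::xml_find_all(rx, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (!length(refs)) return(numeric(0))
      sp <- vapply(refs, .xattr, character(1), "species")
      co <- suppressWarnings(as.numeric(vapply(refs, .xattr, character(1), "stoichiometry")))
      co[is.na(co)] <- 1
      stats::setNames(sign * co, sp)
    }
    s <- c(side("listOfReactants", -1), side("listOfProducts", +1))
    # boundary-condition species are outside the balanced system
    s <- s[!boundary[names(s)]]
    if (!length(s))
      .formatError(sprintf("%s: reaction %s has no (non-boundary) species", basename(path), ids[i]))
    agg <- tapply(unname(s), names(s), sum)
    s <- stats::setNames(as.numeric(agg), names(agg))
    stoich[[i]] <- s[s != 0]
    if (!length(stoich[[i]]))
      .formatError(sprintf("%s: reaction %s has empty net stoichiometry", basename(path), ids[i]))

    # bounds: fbc parameter refs, else L2 kinetic-law parameters, else defaults
    lbRef <- .xattr(rx, "lowerFluxBound"); ubRef <- .xattr(rx, "upperFluxBound")
    kl <- .xfind(rx, "kineticLaw")
    klv <- numeric(0)
    if (length(kl)) {
      kp <- .xfind(kl[[1]], "parameter")
      klv <- stats::setNames(
        suppressWarnings(as.numeric(vapply(kp, .xattr, character(1), "value"))),
        vapply(kp, .xattr, character(1), "id"))
    }
    lb[i] <- if (!is.na(lbRef) && lbRef %in% names(pvals)) pvals[[lbRef]]
             else if ("LOWER_BOUND" %in% names(klv)) klv[["LOWER_BOUND"]]
             else if (rev) -1000 else 0
    ub[i] <- if (!is.na(ubRef) && ubRef %in% names(pvals)) pvals[[ubRef]]
             else if ("UPPER_BOUND" %in% names(klv)) klv[["UPPER_BOUND"]]
             else 1000

    # genes: fbc geneProductAssociation flattened; else GENE_ASSOCIATION notes
    gpa <- .xfind(rx, "geneProductRef")
    if (length(gpa)) {
      gids <- vapply(gpa, .xattr, character(1), "geneProduct")
      mapped <- ifelse(gids %in% names(gpLabel), gpLabel[gids], gids)
      genes[[i]] <- unique(unname(mapped))
    } else {
      notes <- .xfind(rx, "notes")
      genes[[i]] <- character(0)
      if (length(notes)) {
        txt <- xml2::xml_text(notes[[1]])
        mm <- regmatches(txt, regexec("GENE_ASSOCIATION:[[:space:]]*([^\n<]*)", txt))[[1]]
        if (length(mm) == 2L && nzchar(trimws(mm[2]))) {
          toks <- strsplit(gsub("[()]", " ", mm[2]), "[[:space:]]+")[[1]]
          toks <- toks[nzchar(toks) & !tolower(toks) %in% c("and", "or")]
          genes[[i]] <- unique(toks)
        }
      }
    }
  }

  # declared objective (fbc)
  if (is.null(objective)) {
    lobj <- .xfind(modelNode, "listOfObjectives")
    if (length(lobj)) {
      active <- .xattr(lobj[[1]], "activeObjective")
      objs <- .xfind(lobj[[1]], "objective")
      pick <- if (!is.na(active) && length(objs)) {
        oid <- vapply(objs, .xattr, character(1), "id")
        objs[which(oid == active)]
      } else objs
      if (length(pick)) {
        fo <- .xfind(pick[[1]], "fluxObjective")
        if (length(fo)) objective <- .xattr(fo[[1]], "reaction")
      }
    }
  }
  if (is.null(objective) || is.na(objective))
    .configError(sprintf(
      "%s declares no objective; supply one explicitly (objective = / --objective)",
      basename(path)))
  if (!objective %in% ids)
    .configError(sprintf("objective reaction %s not present in %s", objective, basename(path)))

  .newModel(ids, stoich, lb, ub, genes, objective,
            metNames = metNames, metComp = metComp)
}

#' Read a metabolic model, format sniffed from the extension
#'
#' `.xml`/`.sbml` dispatch to [readSBMLModel()]; anything else to
#' [readTabularModel()].
#'
#' @inheritParams readSBMLModel
#' @return a [MetabolicModel-class].
#' @export
readModel <- function(path, objective = NULL) {
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
    readSBMLModel(path, objective = objective)
  else
    readTabularModel(path)
}

# ---- flux tables -----------------------------------------------------------

#' Write a flux distribution as TSV
#'
#' Two columns (`reaction_id`, `flux`) at full precision, preceded by a header
#' comment recording the achieved objective value, the solver status, and a
#' hash of the configuration used (for provenance). [readFluxTable()] restores
#' the distribution bit-exactly.
#'
#' @param flux a [FluxDistribution-class].
#' @param path output path.
#' @param config optional [TargetingConfig-class] whose hash is recorded.
#' @return invisibly, `path`.
#' @export
writeFluxTable <- function(flux, path, config = NULL) {
  hdr <- sprintf("# objective=%s status=%s config=%s",
                 .fmtNum(flux@objectiveValue), flux@status,
                 if (is.null(config)) "NA" else configHash(config))
  lines <- c(hdr, "reaction_id\tflux",
             sprintf("%s\t%.17e", names(flux@fluxes), flux@fluxes))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) .ioError(sprintf("cannot write flux table to %s", path))
  invisible(path)
}

#' @rdname writeFluxTable
#' @return `readFluxTable` returns the [FluxDistribution-class] stored in the
#'   file.
#' @export
readFluxTable <- function(path) {
  if (!file.exists(path)) .ioError(sprintf("flux table not found: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")][1]
  # non-optimal distributions store a literal NA objective
  obj <- suppressWarnings(as.numeric(sub(".*objective=([^ ]+).*", "\\1", hdr)))
  status <- sub(".*status=([^ ]+).*", "\\1", hdr)
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]  # column header
  fl <- numeric(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    fl <- stats::setNames(as.numeric(vapply(parts, `[`, character(1), 2)),
                          vapply(parts, `[`, character(1), 1))
  }
  new("FluxDistribution", fluxes = fl, objectiveValue = obj, status = status)
}
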