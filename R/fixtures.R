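# Deterministic toy networks covering every coupling regime the method
# distinguishes: full coupling (CHAIN3), full compensation and degenerate
# optima (PARALLEL), selective vulnerability (SELECTIVE), futile cycles
# (CYCLE), and seeded random sparse networks with a planted growth pathway
# (RANDOM). They stand in for a genome-scale reconstruction in tests and
# examples; they make no attempt at biochemical realism (no compartments, no
# cofactors). All bounds bracket zero, so scaling a feasible distribution by
# any fraction in [0, 1] stays feasible — the property that pins the
# throttling-ratio lower bound.

.fixtureNames <- c("CHAIN3", "PARALLEL", "SELECTIVE", "CYCLE", "RANDOM")

.fixtureTable <- function(rows) {
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

.rw <- function(id, eq, lb = "", ub = "", genes = "", obj = "0")
  list(reaction_id = id, equation = eq, lower_bound = lb, upper_bound = ub,
       genes = genes, objective = obj)

#' Build a named toy model
#'
#' @param scenario one of `"CHAIN3"` (uptake -> A -> B -> biomass, gene `g1` on
#'   the internal step), `"PARALLEL"` (CHAIN3 plus a second, independently
#'   gene-controlled A -> B route), `"SELECTIVE"` (biomass needs B and C; C
#'   comes either from an external transporter `T`, gene `gT`, or internal
#'   synthesis `S`, gene `gS`, which burns two substrate units per C so that a
#'   cell expressing the transporter prefers import, as real cells do), `"CYCLE"` (PARALLEL plus a stoichiometrically
#'   balanced two-reaction futile cycle), or `"RANDOM"` (seeded sparse random
#'   network with a planted feasible chain to biomass).
#' @param seed RNG seed, used by `"RANDOM"` only; named scenarios are
#'   seed-independent and bit-reproducible.
#' @param size number of reactions for `"RANDOM"` (>= 6).
#' @return a validated [MetabolicModel-class].
#' @examples
#' makeFixtureModel("SELECTIVE")
#' @export
makeFixtureModel <- function(scenario = c("CHAIN3", "PARALLEL", "SELECTIVE",
                                          "CYCLE", "RANDOM"),
                             seed = 1L, size = 20L) {
  scenario <- match.arg(scenario)
  base <- list(
    .rw("EX_A", "A ->", lb = "-10"),
    .rw("R1", "A -> B", genes = "g1"),
    .rw("BIOMASS", "B ->", obj = "1")
  )
  rows <- switch(scenario,
    CHAIN3 = base,
    PARALLEL = append(base, list(.rw("R2", "A -> B", genes = "g2")), after = 2),
    CYCLE = append(base, list(
      .rw("R2", "A -> B", genes = "g2"),
      .rw("C1", "B -> D"),
      .rw("C2", "D -> B")), after = 2),
    SELECTIVE = list(
      .rw("EX_A", "A ->", lb = "-10"),
      .rw("EX_Cext", "Cext ->", lb = "-10"),
      .rw("R1", "A -> B", genes = "g1"),
      .rw("S", "2 A -> C", genes = "gS"),
      .rw("T", "Cext -> C", genes = "gT"),
      .rw("BIOMASS", "1 B + 1 C ->", obj = "1")
    ),
    RANDOM = return(.randomModel(seed, size))
  )
  .modelFromTable(.fixtureTable(rows), source = scenario)
}

.randomModel <- function(seed, size) {
  size <- as.integer(size)
  if (is.na(size) || size < 6L)
    .validationError("RANDOM fixture needs size >= 6")
  .withSeed(as.integer(seed), {
    chainLen <- max(2L, size %/% 2L)          # planted pathway guarantees growth
    mets <- paste0("M", seq_len(chainLen))
    rows <- list(.rw("EX_M1", "M1 ->", lb = "-10"))
    for (i in seq_len(chainLen - 1L))
      rows[[length(rows) + 1L]] <- .rw(sprintf("P%d", i),
                                       sprintf("%s -> %s", mets[i], mets[i + 1L]),
                                       genes = sprintf("gp%d", i))
    rows[[length(rows) + 1L]] <- .rw("BIOMASS", sprintf("%s ->", mets[chainLen]), obj = "1")
    extra <- size - length(rows)
    genePool <- paste0("gx", 1:5)
    for (j in seq_len(max(0L, extra))) {
      ab <- sample(mets, 2L)
      reversible <- stats::runif(1) < 0.5
      rows[[length(rows) + 1L]] <- .rw(
        sprintf("X%d", j),
        sprintf("%s %s %s", ab[1], if (reversible) "<=>" else "->", ab[2]),
        genes = if (stats::runif(1) < 0.7) sample(genePool, 1L) else "")
    }
    .modelFromTable(.fixtureTable(rows), source = sprintf("RANDOM(seed=%d)", seed))
  })
}

#' Expression profiles matched to a toy model
#'
#' Returns a target/reference pair of [ExpressionProfile-class] objects. For
#' `"SELECTIVE"` the target lacks expression of the transporter gene `gT`
#' (mirroring a cell that cannot import a metabolite and must synthesise it),
#' while the reference expresses it; this is the mechanism that opens a
#' selective therapeutic window. All other scenarios return the same profile
#' twice: 37 RPKM on `g1` for `"CHAIN3"` (giving growth 0.0027 x 40 = 0.108 at
#' the default configuration) and 5000 RPKM on both route genes for
#' `"PARALLEL"`/`"CYCLE"`, which makes substrate uptake (not enzyme capacity)
#' limiting so that the two routes are genuinely redundant. `"RANDOM"` draws
#' uniform RPKM on \[20, 100\] for every gene in the model, duplicated into
#' both profiles.
#'
#' @inheritParams makeFixtureModel
#' @return list with elements `target` and `reference`.
#' @export
makeFixtureProfiles <- function(scenario = c("CHAIN3", "PARALLEL", "SELECTIVE",
                                             "CYCLE", "RANDOM"),
                                seed = 1L, size = 20L) {
  scenario <- match.arg(scenario)
  dup <- function(v) list(target = expressionProfile("target", v),
                          reference = expressionProfile("reference", v))
  switch(scenario,
    CHAIN3 = dup(c(g1 = 37)),
    PARALLEL = dup(c(g1 = 5000, g2 = 5000)),
    CYCLE = dup(c(g1 = 5000, g2 = 5000)),
    SELECTIVE = list(
      target = expressionProfile("target", c(g1 = 50, gS = 50, gT = 0)),
      reference = expressionProfile("reference", c(g1 = 50, gS = 50, gT = 50))),
    RANDOM = {
      m <- .randomModel(seed, size)
      genes <- sort(unique(unlist(m@genes, use.names = FALSE)))
      vals <- .withSeed(as.integer(seed) + 1L,
                        stats::setNames(stats::runif(length(genes), 20, 100), genes))
      dup(vals)
    })
}

#' Write a fixture scenario to disk
#'
#' Writes the tabular model (`model.tsv`) and both expression profiles
#' (`target.csv`, `reference.csv`) of a scenario into a directory, so the
#' command-line pipeline can be exercised end to end without external data.
#'
#' @inheritParams makeFixtureModel
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (named character vector).
#' @export
writeFixture <- function(scenario, dir, seed = 1L, size = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- makeFixtureModel(scenario, seed = seed, size = size)
  pr <- makeFixtureProfiles(scenario, seed = seed, size = size)
  paths <- c(model = file.path(dir, "model.tsv"),
             target = file.path(dir, "target.csv"),
             reference = file.path(dir, "reference.csv"))
  writeTabularModel(m, paths[["model"]])
  # one column per sample, HPA-style: header is the sample id
  for (nm in c("target", "reference")) {
    v <- pr[[nm]]@values
    df <- data.frame(gene = names(v), x = unname(v), check.names = FALSE)
    names(df)[2] <- pr[[nm]]@sampleId
    utils::write.csv(df, paths[[nm]], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
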