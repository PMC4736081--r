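#' @include io.R
NULL

#' Run a declarative construct-build workflow
#'
#' Executes a YAML (or pre-parsed list) workflow: a `seed` for the fixture
#' registry and a list of `constructs`, each an operation over previously
#' declared ids. Supported operations:
#'
#' * `domesticate`: `protospacer`, optional `mode` (`D`/`M`/`poly`).
#' * `cassette`: `duplex` (id), into `destination` (`alpha1`, `alpha2`,
#'   `omega1`, `omega2`).
#' * `polycistron`: `targets` (list of 20-nt strings), `destination`.
#' * `cas9_tu` / `marker_tu`: a synthetic TU in `destination`.
#' * `binary`: `a`, `b` (ids of hosted level >= 1 parts), `destination`.
#'
#' Fixture parts (promoter, scaffold, vectors, level -1 slots) are generated
#' deterministically from the seed. Every emitted construct can be re-derived
#' from its listed inputs, making the report a full assembly genealogy.
#'
#' @param spec path to a workflow YAML file, or an equivalent list.
#' @param outDir optional directory; when given, every hosted construct is
#'   written as GenBank and the report as JSON.
#' @param cfg toolbox configuration.
#' @return list with `constructs` (named list of results) and `report`
#'   (steps, per-construct sizes and predicted validation digests, binary
#'   step count).
#' @export
runWorkflow <- function(spec, outDir = NULL, cfg = gbConfig()) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  seed <- if (!is.null(spec$seed)) spec$seed else 1L
  fx <- fixtureConfig(seed = seed)
  steps <- spec$constructs
  registry <- list()
  report <- list(seed = seed, steps = list(), n_binary = 0L)

  if (length(steps) == 0L)
    return(list(constructs = list(), report = report))

  dest <- function(name) {
    switch(name,
      alpha1 = makeVector("alpha", 1L, fx, cfg = cfg),
      alpha2 = makeVector("alpha", 2L, fx, cfg = cfg),
      omega1 = makeVector("omega", 1L, fx, cfg = cfg),
      omega2 = makeVector("omega", 2L, fx, cfg = cfg),
      .gbValidationError(paste0("unknown destination: ", name)))
  }
  fetch <- function(id) {
    if (is.null(registry[[id]]))
      .gbValidationError(paste0("unknown construct id: ", id))
    registry[[id]]
  }

  prom <- NULL
  scaf <- NULL
  for (st in steps) {
    if (is.null(st$id) || is.null(st$op))
      .gbValidationError("every workflow step needs an 'id' and an 'op'")
    res <- switch(st$op,
      domesticate = {
        mode <- switch(if (is.null(st$mode)) "D" else st$mode,
                       D = "monocistronic_D", M = "monocistronic_M",
                       poly = "polycistronic")
        domesticateTarget(st$protospacer, mode, cfg = cfg)
      },
      cassette = {
        if (is.null(prom)) prom <- makePromoterPart(fx, cfg)
        if (is.null(scaf)) scaf <- makeScaffoldPart(fx, cfg = cfg)
        assembleGuideCassette(prom, fetch(st$duplex), scaf,
                              dest(st$destination), partId = st$id,
                              cfg = cfg)
      },
      polycistron = {
        if (is.null(prom)) prom <- makePromoterPart(fx, cfg)
        n <- length(st$targets)
        design <- polycistronDesign(
          unlist(st$targets), promoter = prom,
          slotParts = lapply(seq_len(n), makeSlotPart, nSlots = n, fx = fx,
                             cfg = cfg),
          label = st$id)
        buildPolycistron(design, dest(st$destination), partId = st$id,
                         cfg = cfg)
      },
      cas9_tu = makeCas9TU(dest(st$destination), fx, cfg),
      marker_tu = makeMarkerTU(dest(st$destination), fx, cfg),
      binary = {
        report$n_binary <- report$n_binary + 1L
        binaryAssemble(fetch(st$a), fetch(st$b), dest(st$destination),
                       partId = st$id, cfg = cfg)
      },
      .gbValidationError(paste0("unknown workflow op: ", st$op)))
    registry[[st$id]] <- res
    entry <- list(id = st$id, op = st$op,
                  inputs = unlist(st[names(st) %in%
                                       c("a", "b", "duplex", "targets",
                                         "protospacer", "destination")]))
    if (is(res, "GBPart")) {
      entry$length_bp <- nchar(res@molecule@seq)
      entry$vector_class <- res@vectorClass
      entry$fusion_sites <- res@fusions
      pat <- predictBands(res@molecule, "BsmBI", cfg = cfg)
      entry$validation_digest <- list(
        enzyme = "BsmBI",
        bands = if (pat@uncut) "uncut" else paste(pat@bands, collapse = "-"))
      if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeGenBank(res@molecule, file.path(outDir,
                                             paste0(st$id, ".gb")))
      }
    }
    report$steps[[length(report$steps) + 1L]] <- entry
  }
  if (!is.null(outDir))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  list(constructs = registry, report = report)
}
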