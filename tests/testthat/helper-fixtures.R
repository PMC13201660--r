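# Small in-code fixtures shared across the suite.

# 1000-nt toy reference with a handful of forced U positions
tinyRef <- function(uAt = c(150L, 400L, 700L)) {
  syntheticReference(length = 1000L, name = "toyref", seed = 11L, uAt = uAt)
}

# toy catalogue on the 1000-nt reference: two "mature" species, one
# precursor spanning both, one spacer
tinyTemplates <- function() {
  TemplateSet(name = c("pre", "matA", "matB", "spacer"),
              start = c(1L, 101L, 501L, 301L),
              end = c(900L, 300L, 800L, 500L),
              category = c("precursor", "mature", "mature",
                           "spacer-fragment"),
              refLength = 1000L)
}

# read set built from explicit spans (optionally with per-read extras)
makeReads <- function(start, end, refLength = 1000L, refname = "toyref",
                      ...) {
  RiboReadSet(start, end, refLength = refLength, refname = refname, ...)
}

# the full-size catalogue paired with a synthetic 45SN1-length reference
fullTemplates <- function() defaultTemplates()

# deterministic planted pseudouridine catalogue on the mature rRNA
# intervals: n positions evenly spaced strictly inside each interval
psiCatalogue <- function(ts = defaultTemplates(),
                         n = c(`18S` = 42L, `28S` = 60L, `5.8S` = 2L)) {
  rng <- templateRanges(ts)
  do.call(rbind, lapply(names(n), function(t) {
    s <- IRanges::start(rng[t]) + 5L
    e <- IRanges::end(rng[t]) - 5L
    data.frame(rrna = t,
               position = as.integer(round(seq(s, e, length.out = n[[t]]))),
               stringsAsFactors = FALSE)
  }))
}
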