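# Independent oracles and small polycyclic fixtures used across tests.

# brute-force perfect-matching counter (exponential; fixtures <= 30 atoms).
# Entirely independent of the package's determinant-based Kekule counting.
count_matchings_bruteforce <- function(g) {
  n <- nAtoms(g)
  if (n %% 2L == 1L) return(0L)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nBonds(g))) {
    a <- bonds(g)[r, 1]; b <- bonds(g)[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  recurse <- function(matched) {
    free <- which(!matched)
    if (!length(free)) return(1L)
    v <- free[1]
    total <- 0L
    for (w in adj[[v]]) {
      if (!matched[w]) {
        matched[c(v, w)] <- TRUE
        total <- total + recurse(matched)
        matched[c(v, w)] <- FALSE
      }
    }
    total
  }
  recurse(rep(FALSE, n))
}

ring_graph <- function(n) molecularGraph(cbind(1:n, c(2:n, 1)))

benzene <- function() ring_graph(6)

# catacondensed acenes and pyrene via the honeycomb template machinery
# (template graphs are themselves benzenoid skeletons)
template_graph <- function(tmpl, tag = NA_character_) {
  molecularGraph(tmpl$edges, nAtoms = nrow(tmpl$coords),
                 coords = tmpl$coords, familyTag = tag)
}

naphthalene <- function()
  template_graph(buildTemplate(fractalSpec("RCF", n = 1, m = 2)), "naphthalene")

anthracene <- function()
  template_graph(buildTemplate(fractalSpec("RCF", n = 1, m = 3)), "anthracene")

# all specs with sizes small enough for exhaustive property sweeps
small_specs <- function(nmax = 3) {
  specs <- list()
  for (n in 1:nmax) {
    specs <- c(specs, list(fractalSpec("ZHCF", n), fractalSpec("AHCF", n)))
    for (m in 1:nmax) specs <- c(specs, list(fractalSpec("RCF", n, m = m)))
  }
  specs
}
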