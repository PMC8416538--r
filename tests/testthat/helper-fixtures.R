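# shared fixtures, built lazily and cached for the whole test run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# a mid-sized single-trait panel used by the GBLUP / MT / MTME limit tests
std_panel <- function() fixture("std_panel", function() {
  cfg <- sim_config(n_lines = 100, n_markers = 800, n_families = 10,
                    n_envs = 2, traits = "A", h2 = 0.5, seed = 5)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  b <- env_blues_table(sim$plots)
  d <- b[b$env == "E1", ]
  list(cfg = cfg, geno = g, sim = sim, G = sim$G, blues = b,
       y = stats::setNames(d$value, d$line))
})

# the season_high two-trait panel used by the CV-scheme tests
high_panel <- function() fixture("high_panel", function() {
  sc <- make_paper_like_scenarios(n_lines = 150, n_markers = 1000,
                                  seed = 3)$season_high
  g <- simulate_genotypes(sc)
  sim <- simulate_phenotypes(g, sc)
  list(cfg = sc, sim = sim, G = sim$G, blues = env_blues_table(sim$plots))
})

# the 5-line toy dosage matrix exercising both marker QC rules
qc_toy <- function() {
  dos <- cbind(m1 = c(0, 0, 0, 0, 0),
               m2 = c(2, 2, 2, 2, 0),
               m3 = c(1, NA, NA, NA, 0),
               m4 = c(0, 1, 2, 1, 0))
  rownames(dos) <- paste0("l", 1:5)
  marker_set(dos, chrom = rep("chr1", 4), pos = 1:4)
}

# tiny biallelic VCF written to a temp file
write_toy_vcf <- function(path, multiallelic = FALSE) {
  alt2 <- if (multiallelic) "A,G" else "A"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\tsnp1\tG\tT\t.\tPASS\t.\tGT\t0/0\t1/1",
    paste0("chr1\t200\tsnp2\tC\t", alt2, "\t.\tPASS\t.\tGT\t0/1\t./."))
  writeLines(lines, path)
  path
}
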