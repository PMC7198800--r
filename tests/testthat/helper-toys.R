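# Shared fixtures (built in code) and independent oracles.

# Linear chain: EX_A (uptake <= bound) -> transport -> A->B -> biomass.
# Optimal growth equals the uptake bound.
toy_chain <- function(uptake = 10) {
  net <- metabolic_network(
    "chain",
    list(metabolite("A_e", compartment = "e"), metabolite("A_c"),
         metabolite("B_c")),
    list(reaction("EX_A", c(A_e = -1), 0, 1000, is_exchange = TRUE),
         reaction("T_A", c(A_e = -1, A_c = 1)),
         reaction("R_AB", c(A_c = -1, B_c = 1)),
         reaction("BIO", c(B_c = -1), is_biomass = TRUE)))
  list(net = net,
       medium = medium_condition("A", c(EX_A = uptake), "EX_A"))
}

# Branched: routes of biomass yield 1 and 2 per unit A; optimum takes
# the yield-2 route, growth = 2 * uptake.
toy_branched <- function(uptake = 5) {
  net <- metabolic_network(
    "branched",
    list(metabolite("A_e", compartment = "e"), metabolite("A_c"),
         metabolite("B_c")),
    list(reaction("EX_A", c(A_e = -1), 0, 1000, is_exchange = TRUE),
         reaction("T_A", c(A_e = -1, A_c = 1)),
         reaction("R1", c(A_c = -1, B_c = 1)),
         reaction("R2", c(A_c = -1, B_c = 2)),
         reaction("BIO", c(B_c = -1), is_biomass = TRUE)))
  list(net = net,
       medium = medium_condition("A", c(EX_A = uptake), "EX_A"))
}

# Two nitrogen routes feeding a common biomass precursor; used for
# negative-gapfilling scenarios.
toy_two_sources <- function(shared_step = FALSE) {
  mets <- list(metabolite("n1_e", compartment = "e"),
               metabolite("n2_e", compartment = "e"),
               metabolite("n1_c"), metabolite("n2_c"),
               metabolite("x_c"), metabolite("p_c"))
  rxns <- list(
    reaction("EX_n1", c(n1_e = -1), 0, 1000, is_exchange = TRUE),
    reaction("EX_n2", c(n2_e = -1), 0, 1000, is_exchange = TRUE),
    reaction("T_n1", c(n1_e = -1, n1_c = 1)),
    reaction("T_n2", c(n2_e = -1, n2_c = 1)),
    reaction("BIO", c(p_c = -1), is_biomass = TRUE))
  if (shared_step) {
    rxns <- c(rxns, list(
      reaction("R_n1x", c(n1_c = -1, x_c = 1)),
      reaction("R_n2x", c(n2_c = -1, x_c = 1)),
      reaction("R_conv", c(x_c = -1, p_c = 1))))
  } else {
    rxns <- c(rxns, list(
      reaction("R_n1p", c(n1_c = -1, p_c = 1)),
      reaction("R_n2p", c(n2_c = -1, p_c = 1))))
  }
  list(net = metabolic_network("two_src", mets, rxns),
       med1 = medium_condition("n1", c(EX_n1 = 10), "EX_n1"),
       med2 = medium_condition("n2", c(EX_n2 = 10), "EX_n2"))
}

# Random small gapfill instances: a chain universe whose draft lost a
# few interior steps; db small enough for exhaustive search.
random_gapfill_instance <- function(seed) {
  withr::with_seed(seed, {
    len <- sample(3:5, 1)
    mets <- c(list(metabolite("S_e", compartment = "e")),
              lapply(0:len, function(i) metabolite(paste0("m", i))))
    chain <- lapply(seq_len(len), function(i)
      reaction(sprintf("STEP_%02d", i),
               stats::setNames(c(-1, 1),
                               c(paste0("m", i - 1), paste0("m", i)))))
    base <- list(
      reaction("EX_S", c(S_e = -1), 0, 1000, is_exchange = TRUE),
      reaction("T_S", c(S_e = -1, m0 = 1)))
    bio <- reaction("BIO", stats::setNames(-1, paste0("m", len)),
                    is_biomass = TRUE)
    # bypass reactions create alternative, sometimes shorter routes
    n_bypass <- sample(2:4, 1)
    bypass <- lapply(seq_len(n_bypass), function(i) {
      ft <- sort(sample(0:len, 2))
      reaction(sprintf("BYP_%02d", i),
               stats::setNames(c(-1, 1),
                               c(paste0("m", ft[1]),
                                 paste0("m", ft[2]))))
    })
    db <- universal_db("db", mets, c(base, chain, bypass))
    lost <- sample(len, sample(1:2, 1))
    draft <- metabolic_network("draft", mets,
                               c(base, chain[-lost], list(bio)))
    list(draft = draft, db = db,
         medium = medium_condition("S", c(EX_S = 10), "EX_S"))
  })
}

# Independent oracle: exhaustive minimum-cardinality gapfill search
# over all db subsets (instances are built small enough to enumerate).
oracle_min_gapfill <- function(draft, db, medium, epsilon = 1e-3) {
  cand <- sort(setdiff(names(db$reactions), names(draft$reactions)))
  for (k in 0:length(cand)) {
    combos <- if (k == 0) list(character(0)) else
      utils::combn(cand, k, simplify = FALSE)
    for (s in combos) {
      net <- if (length(s))
        add_reactions(draft, db$reactions[s], from = db) else draft
      if (predicts_growth(net, medium, epsilon)) return(s)
    }
  }
  NULL
}

# Independent oracle: Benjamini-Hochberg step-up written from the
# definition (sort, adjust by m/rank, enforce monotonicity, cap at 1).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Closed-form chi-square survival function for even df (series sum),
# used as the independent check of Fisher's combined probability.
oracle_chisq_upper_even_df <- function(x, df) {
  stopifnot(df %% 2 == 0)
  k <- df / 2
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}
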