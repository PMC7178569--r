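# Shared fixtures, generated in code. A small hand-picked SMILES panel
# covering aromatics, bracket atoms, halogens, charges, multiple rings and
# acyclic molecules, plus a cached synthetic corpus for property tests.

FIXTURE_SMILES <- c(
  "CCO", "OCC", "C", "O", "N#Cc1ccc(Cl)cc1Br", "Cc1cc[nH]c1",
  "CC(=O)Oc1ccccc1C(=O)O", "[O-]C(=O)C", "C1CCCC1", "C1CCOC1CN",
  "c1ccncc1", "Cc1ccccc1", "BrCCl", "FC(F)F", "C1.C1", "CCS",
  "c1ccc2ccccc2c1", "[13CH4]", "CC(C)(C)C", "C%10CCCC%10")

# One shared synthetic corpus per test run (seeded, deterministic).
fixture_corpus <- local({
  corpus <- NULL
  function(n = 150L, seed = 402L) {
    key <- paste0(n, "_", seed)
    if (is.null(corpus[[key]])) {
      corpus[[key]] <<- generate_corpus(synth_spec(n_molecules = n, seed = seed))
    }
    corpus[[key]]
  }
})

# Tiny deterministic vocabulary over the fixture panel.
fixture_vocab <- function(smiles = FIXTURE_SMILES) {
  build_vocab(lapply(smiles, tokenize_smiles))
}

# Tiny encoder for fast model tests: all dropouts off unless asked.
test_encoder <- function(dropout_mult = 0, embedding_dim = 8L,
                         hidden_dim = 12L, n_layers = 3L) {
  encoder_config(embedding_dim = embedding_dim, hidden_dim = hidden_dim,
                 n_layers = n_layers, dropout_mult = dropout_mult)
}
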