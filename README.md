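# clinconex

Ensemble clinical concept extraction with weighted integration of
pluggable NER backends.

## The problem

Clinical free text — discharge letters, progress notes — carries most of
the information in a patient record, and extracting standardized concepts
(medical conditions, pharmaceutical drugs) from it usually means deploying
and maintaining a heavyweight NLP stack. An alternative is to treat
named-entity recognition as a commodity: send the text to several
general-purpose extraction services, and combine their answers. Individual
general-purpose extractors are mediocre on clinical text; the interesting
part is the integration. `clinconex` implements that integration layer,
together with everything needed to run and evaluate it fully offline:
deterministic mock extractors, NegEx-style negation filtering, a local
UMLS-like concept lexicon, an evaluation and tuning harness, and a
synthetic corpus generator.

## The method

Each extractor returns surface mentions. Mentions are negation-filtered
(switch κ), then normalized against a concept lexicon that returns up to
10 ranked standardized codes per surface (CUI-style), most similar first.
Integration uses a **double weight system**:

1. **Term similarity.** For two terms with ranked code lists, let α be the
   fraction of shared codes over the full top-10 lists and β the fraction
   shared among both top-3 lists. The pair's similarity weight is

       w = α/4 + 3β/4  ∈ [0, 1]

   and the terms are considered the same entity when `w > γ`. Merging is
   closed transitively, so entities are the connected components of the
   pairwise-similarity graph.

2. **Extractor reliability.** Each extractor i gets a weight
   `ω_i = F1_i / Σ_j F1_j`, its held-out F1 score sum-normalized over the
   roster. A merged entity's cumulative weight is the sum of ω over the
   *distinct* extractors that found it, and the entity is accepted exactly
   when that sum is strictly greater than θ.

Defaults are γ = 0.1, θ = 0.35, κ = off; `run_tune()` grid-searches all
three. Evaluation counts entity-level TP/FP/FN per document (greedy
one-to-one matching, code matches before surface matches) and reports
micro-averaged precision, recall and F1.

## Worked example

Six mock extractors process one note. Two of them know the surface
"hematoma"; all six know "orthostatic hypotension" and "fracture". With
uniform weights ω = 1/6, θ = 0.35 and the negation filter on:

```r
library(clinconex)

lexicon <- concept_lexicon(list(
  hematoma = list(list(code = "C0018944"), list(code = "C0332606")),
  "orthostatic hypotension" = list(list(code = "C0020651"), list(code = "C0600109")),
  fracture = list(list(code = "C0016658"))))

note <- document("note1",
  "Fall during the night, multiple hematomas. Orthostatic hypotension proven. No fracture.")

fixture_full <- list(hematoma = "medical_condition",
                     "orthostatic hypotension" = "medical_condition",
                     fracture = "medical_condition")
fixture_partial <- fixture_full[-1]
roster <- c(
  lapply(paste0("api", 1:2), function(id) extractor_spec(id, "mock", fixture = fixture_full)),
  lapply(paste0("api", 3:6), function(id) extractor_spec(id, "mock", fixture = fixture_partial)))

pl <- pipeline_config(list(note), lexicon, roster,
                      config = integration_config(kappa = TRUE, gamma = 0.1, theta = 0.35))
res <- run_extract(pl)
print(res[[1]])
for (e in res[[1]]$rejected) print(e)
print(attr(res, "stage_counts"))
```

prints

```
<extraction result 'note1'>: 1 accepted, 1 rejected
<entity 'Orthostatic hypotension' CUI:C0020651> extractors {api1,api2,api3,api4,api5,api6} weight 1.000
<entity 'hematomas' CUI:C0018944> extractors {api1,api2} weight 0.333
  doc_id extracted negated after_filter encoded merged accepted
1  note1        14       6            8       8      2        1
```

Reading it: "hematomas" (plural surface, singular lexicon entry) was found
by only 2 of 6 extractors — cumulative weight 1/3 ≤ θ, so it is treated as
a false extraction and rejected. "Orthostatic hypotension" carries weight
1.0 and is accepted. "No fracture" was extracted 6 times but every mention
fell inside a NegEx span (6 of the 14 raw mentions negated) and the κ
filter removed them before integration.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "clinconex.R", package = "clinconex"))')
Rscript "$CLI" simulate --seed 7 --n-docs 20 --out data/   # synthetic study
Rscript "$CLI" extract  --config run.yaml
Rscript "$CLI" evaluate --config run.yaml
Rscript "$CLI" tune     --config run.yaml --gammas 0.1,0.3 --thetas 0.2,0.35,0.5
```

The config format is documented at the top of the script. REST extractor
credentials come from the environment or the config file, never from
flags.

## Scope notes

Adapters for live REST NER services are shipped as a contract
(`build_rest_request()` / `parse_rest_response()` plus an injectable
transport); nothing in the tests or the acceptance script touches the
network. The concept lexicon is a local stand-in for a metathesaurus
lookup service with the same top-10 ranked interface. De-identification is
a pass-through hook (`deidentify` in `pipeline_config()`), not an
implementation.
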