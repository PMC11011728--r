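# PhaseFusion

Dual-tower multimodal Transformers for surgical phase recognition, at
desk scale and with no external data or pretrained weights.

## The problem

Laparoscopic cholecystectomy (gallbladder removal) proceeds through
seven ordered phases — preparation, Calot's triangle dissection,
clipping and cutting, gallbladder dissection, gallbladder packaging,
cleaning and coagulation, gallbladder retraction. Recognising the
current phase from the endoscopic video supports OR workflow analysis,
skill assessment and post-hoc reporting. PhaseFusion implements a
vision-language approach for frame-level phase recognition: each video
frame is paired with a short text description, both modalities are
embedded and encoded separately, and a classifier reads the fused
representation.

## The model

Two independent towers produce embedding sequences:

* an image tower in the ViT style — the frame is cut into non-overlapping
  16x16 patches, linearly projected, given sinusoidal positional
  encodings and passed through Transformer blocks; global average
  pooling yields a fixed-size vector;
* a text tower — lowercased whitespace tokens are looked up in a learned
  embedding table and given positional encodings.

Each modality's sequence then passes through its own convolution-free
Transformer encoder (post-norm blocks of multi-head self-attention and
position-wise feed-forward layers). The mean-pooled encoder outputs go
through per-modality projection heads (two fully connected layers with
a ReLU, then a linear map) into a joint embedding space. The towers,
encoders and heads are trained jointly with the multimodal contrastive
(InfoNCE) objective

    L = -(1/n) * sum_i log[ exp(sim(x_i, y_i)/tau)
                            / sum_j exp(sim(x_i, y_j)/tau) ]

where `sim` is cosine similarity, `tau` a temperature (default 0.1),
and the denominator runs over the in-batch texts (a symmetric variant
averaging both retrieval directions is available and used by the desk
preset). A multilayer perceptron trained with cross-entropy on the
concatenated projected vectors recognises the phase; its softmax output
is the 7-class phase distribution. A one-encoder ablation (both
modality sequences concatenated into a single shared encoder, trained
end-to-end with cross-entropy) and a paired t-test over cross-validation
folds quantify the value of the two-encoder design.

Because real cholecystectomy videos and pretrained ViT/BERT weights are
out of scope, the package ships a seeded synthetic generator that
emulates the structure of the public 80-video cholecystectomy corpus:
seven phases per video in procedural order, per-phase durations drawn
from gamma distributions moment-matched to the published per-phase
mean and standard deviation (for example 954 +/- 538 s for the Calot's
triangle dissection), phase-specific image motifs degraded by
instrument overlays, smoke and sensor noise, and per-frame template
texts. Externally precomputed embeddings (e.g. from a real ViT or
BERT) can be injected via a documented TSV interface.

## A worked example

```r
library(PhaseFusion)

mf <- benchmarkDataset(seed = 1)     # ~765 frame/text pairs, 10 videos
rec <- manifestRecords(mf)
vocab <- buildVocab(rec$text)
model <- initPhaseModel(vocab, modelConfigList(), seed = 1)

before <- crossModalRetrieval(mf, model, seed = 1)
fit <- trainTowers(mf, model, deskTrainConfig(seed = 1))
after <- crossModalRetrieval(mf, fit$model, seed = 1)
c(before = before, after = after)
#>    before     after
#> 0.3164894 0.9481383

cv <- runCrossval(mf, k = 5, tc = deskTrainConfig(epochs = 8, seed = 1))
cv$aggregate
#>               metric      mean          sd
#> 1           accuracy 0.9966987 0.004737197
#> 2 weighted_precision 0.9972875 0.003848249
#> 3    weighted_recall 0.9966987 0.004737197
```

Contrastive training lifts phase-level in-batch image-to-text retrieval
from near chance to about 0.95, and five-fold cross-validation of the
full pipeline (towers retrained per fold, evaluation on held-out
videos) reaches ~0.997 mean accuracy on the synthetic benchmark. The
weighted recall equals the accuracy by the micro-averaging identity.
Synthetic texts contain a phase keyword by construction, so these
numbers characterise the pipeline on a deliberately learnable task, not
performance on real surgical video.

A command-line wrapper is installed at `exec/phasefusion` with
subcommands `generate`, `train-towers`, `train-classifier`, `evaluate`,
`ablate` and `infer`.

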