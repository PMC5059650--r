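# dermseg

Automated preprocessing and segmentation of pigmented skin lesions in
dermoscopic images, for researchers building melanoma-screening
pipelines and for anyone who needs reproducible lesion masks from raw
dermoscopy photographs.

Dermoscopic images come with artifacts that break naive segmentation:
dark hairs crossing the lesion, gel bubbles, specular highlights,
uneven illumination, and a smooth luminance transition between lesion
and skin. `dermseg` addresses them in three deterministic stages, all
operating on the CIELAB luminance channel L* (unit scale, D65/2°):

1. **Hair removal.** A bank of twelve oriented complex Gabor wavelets
   Φ(u) = exp(i R₀·u) exp(−½|Au|²), A = diag(ε^−1/2, 1), with dilation
   a = 2.5, elongation ε = 3, R₀ = (0, 3) and θ = 0°, 15°, …, 165°,
   is convolved with the inverted luminance; the per-pixel maximum
   modulus is thresholded by Otsu's method into a hair mask, and masked
   pixels are filled by neighbourhood-based region filling (NBRF):
   iterative boundary peeling where each masked pixel takes the mean of
   its unmasked 8-neighbours.
2. **Enhancement.** Illumination is estimated by Gaussian normalized
   convolution over a skin mask (bg = L > 1.2·Otsu(L)), refined on the
   good-fit set |u_L − L| ≤ 0.05, and divided out:
   L_eq = 0.59·L/E_L. After mapping the 1st–99th percentile window
   onto [0, 0.75], an adaptive sigmoid 1/(1 + exp(10(δ − L))) stretches
   lesion/skin contrast, with δ = 0.88 × the centre of the most
   populated bin of a 16-bin luminance histogram (the skin mode).
3. **Segmentation.** Disk median filter (r = 5), grayscale
   opening (r = 7) + morphological reconstruction by dilation
   (8-connectivity), closing/erosion by a small disk, binarization at
   L < Otsu − κ with κ = 0.08, and connected-component filtering
   (area ≥ 20 px and solidity > 0.25, holes filled).

A seedable synthetic dermoscopy generator renders skin, lesion, hairs,
bubbles, specular spots and illumination gradients with pixel-perfect
ground-truth masks, so the whole pipeline is testable offline, and
`evaluate_mask()` reports the pixelwise metrics
TDR = 100·TP/(TP+FN), FPR = 100·FP/(FP+TN), ER = 100·(FP+FN)/N.

## Worked example

```r
library(dermseg)

s <- generate_sample(synth_spec(seed = 7, hairs = list(count = 12),
                                illum_gradient_strength = 0.25))
res <- segment_image(s$image)
print(res)
#> Lesion segmentation: 5992 foreground px in 4 object(s); 0 rejected
#>  label area_px  solidity
#>      1    5735 0.9780014
#>      2      31 0.7560976
#>      3     126 0.8689655
#>      4     100 0.8928571

sum(res$hair_mask & s$hair_truth) / sum(s$hair_truth)   # hair recall
#> [1] 1

print(evaluate_mask(res$lesion_mask, s$lesion_truth))
#> TP 5166  TN 59544  FP 826  FN 0
#> TDR 100.00%  FPR 1.37%  ER 1.26%

res$enhanced$delta      # the per-image sigmoid cut-off
#> [1] 0.5775
```

The printed table lists each connected component that survived the
area/solidity filter with its size and solidity (1 = perfectly convex);
the main lesion is object 1, the smaller kept objects are dark spots
the thresholding also picked up. All 12 drawn hairs were recovered
(recall 1), and the final mask misses no lesion pixel (TDR 100%) while
marking 1.37% of the background as lesion — mostly a thin rim around
the soft lesion boundary.

The same pipeline runs from the shell over files and directories:

```sh
inst/cli/dermseg synth out/fixtures --n 5 --seed 1 --difficulty full
inst/cli/dermseg segment out/fixtures/sample_001/image.png --out out/seg \
    --save-intermediates
inst/cli/dermseg eval out/seg out/truth --out out/summary
```

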