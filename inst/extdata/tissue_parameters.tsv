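name	value	unit	meaning
# SYNTHETIC reconstruction of the continuum (tissue-level) parameter set.
# The original supplementary parameter tables were not available to this
# package; values below are a documented, internally consistent stand-in in
# the style of the bioregulatory fracture-healing model lineage. Units:
# time in days, length in micrometres, growth factors in ng/ml, matrix
# densities in mg/ml, cell densities and oxygen normalised to [0, 1].
Am	0.50	1/day	mesenchymal stem cell proliferation rate
Af	0.30	1/day	fibroblast proliferation rate
Ac	0.15	1/day	chondrocyte proliferation rate
Ab	0.10	1/day	osteoblast proliferation rate
Y1	0.50	1/day	max osteogenic differentiation rate of MSCs (g_b driven)
H1	10	ng/ml	half-saturation of g_b for osteogenic differentiation
Y2	0.40	1/day	max chondrogenic differentiation rate of MSCs (g_c driven)
H2	10	ng/ml	half-saturation of g_c for chondrogenic differentiation
Y3	0.60	1/day	max endochondral replacement rate of chondrocytes
Hmc	20	mg/ml	half-saturation of cartilage density for endochondral replacement
Yf	0.02	1/day	MSC-to-fibroblast differentiation rate
df	0.30	1/day	fibroblast removal rate (oxygenated, ossifying callus)
Hmb	20	mg/ml	half-saturation of bone density for fibroblast removal
db	0.10	1/day	osteoblast decay rate
Pf	3	mg/ml/day	fibrous matrix production rate per unit fibroblast density
Pc	12	mg/ml/day	cartilage matrix production rate per unit chondrocyte density
Pb	8	mg/ml/day	bone matrix production rate per unit osteoblast density
Qf	0.15	ml/(mg day)	fibrous matrix degradation rate by chondro/osteogenic cells
Qc	0.20	ml/(mg day)	cartilage resorption rate by osteoblasts
Km	100	mg/ml	saturation density of each matrix type
Egb	50	ng/ml/day	osteogenic growth factor production rate by osteoblasts
dgb	1	1/day	osteogenic growth factor decay rate
Egc	50	ng/ml/day	chondrogenic growth factor production rate by chondrocytes
dgc	1	1/day	chondrogenic growth factor decay rate
Ggvc	100	ng/ml/day	angiogenic growth factor production rate by hypoxic chondrocytes
Ggvb	2	ng/ml/day	angiogenic growth factor production rate by hypoxic osteoblasts
dgv	1	1/day	angiogenic growth factor decay rate
Sn_ref	40	1/day	reference oxygen release rate per vessel-occupied cell
oxygen_halving	0.5	-	factor applied to Sn_ref (dense-plexus correction)
Qn	2	1/day	oxygen consumption rate per unit total cell density
kn	0.1	-	oxygen half-saturation for hypoxia/oxygenation switches
Dm	250000	um^2/day	MSC random-motility coefficient
Dfb	250000	um^2/day	fibroblast random-motility coefficient
Dg	300000	um^2/day	growth factor diffusion coefficient (g_b, g_c, g_v)
Dn	1000000	um^2/day	oxygen diffusion coefficient
chi_g	1000	um^2 ml/(ng day)	chemotaxis coefficient of MSCs/fibroblasts on growth factors
chi_m	100	um^2 ml/(mg day)	haptotaxis coefficient of MSCs/fibroblasts on total matrix
mf_init	10	mg/ml	initial granulation (fibrous) tissue density
m_threshold	5	mg/ml	matrix density threshold for tissue-type classification
bc_cm	0.3	-	released MSC density at periosteal/marrow borders
bc_cf	0.3	-	released fibroblast density at periosteal/marrow borders
bc_gb	50	ng/ml	osteogenic growth factor level at the cortex interface
bc_gc	50	ng/ml	chondrogenic growth factor level at the degrading bone ends
bc_cm_days	14	day	duration of the MSC/fibroblast release window
bc_gb_days	7	day	duration of the osteogenic growth factor release window
bc_gc_days	10	day	duration of the chondrogenic growth factor release window
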