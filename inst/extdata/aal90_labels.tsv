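label	name	hemisphere	network
PreCG.L	Precentral gyrus	L	other
PreCG.R	Precentral gyrus	R	other
SFGdor.L	Superior frontal gyrus, dorsolateral	L	other
SFGdor.R	Superior frontal gyrus, dorsolateral	R	other
ORBsup.L	Superior frontal gyrus, orbital part	L	DMN
ORBsup.R	Superior frontal gyrus, orbital part	R	DMN
MFG.L	Middle frontal gyrus	L	CEN
MFG.R	Middle frontal gyrus	R	CEN
ORBmid.L	Middle frontal gyrus, orbital part	L	CEN
ORBmid.R	Middle frontal gyrus, orbital part	R	CEN
IFGoperc.L	Inferior frontal gyrus, opercular part	L	other
IFGoperc.R	Inferior frontal gyrus, opercular part	R	other
IFGtriang.L	Inferior frontal gyrus, triangular part	L	CEN
IFGtriang.R	Inferior frontal gyrus, triangular part	R	CEN
ORBinf.L	Inferior frontal gyrus, orbital part	L	other
ORBinf.R	Inferior frontal gyrus, orbital part	R	other
ROL.L	Rolandic operculum	L	other
ROL.R	Rolandic operculum	R	other
SMA.L	Supplementary motor area	L	other
SMA.R	Supplementary motor area	R	other
OLF.L	Olfactory cortex	L	other
OLF.R	Olfactory cortex	R	other
SFGmed.L	Superior frontal gyrus, medial	L	DMN
SFGmed.R	Superior frontal gyrus, medial	R	DMN
ORBsupmed.L	Superior frontal gyrus, medial orbital	L	other
ORBsupmed.R	Superior frontal gyrus, medial orbital	R	other
REC.L	Gyrus rectus	L	other
REC.R	Gyrus rectus	R	other
INS.L	Insula	L	SN
INS.R	Insula	R	SN
ACG.L	Anterior cingulate and paracingulate gyri	L	SN
ACG.R	Anterior cingulate and paracingulate gyri	R	SN
DCG.L	Median cingulate and paracingulate gyri	L	other
DCG.R	Median cingulate and paracingulate gyri	R	other
PCG.L	Posterior cingulate gyrus	L	DMN
PCG.R	Posterior cingulate gyrus	R	DMN
HIP.L	Hippocampus	L	other
HIP.R	Hippocampus	R	other
PHG.L	Parahippocampal gyrus	L	other
PHG.R	Parahippocampal gyrus	R	other
AMYG.L	Amygdala	L	other
AMYG.R	Amygdala	R	other
CAL.L	Calcarine fissure and surrounding cortex	L	other
CAL.R	Calcarine fissure and surrounding cortex	R	other
CUN.L	Cuneus	L	other
CUN.R	Cuneus	R	other
LING.L	Lingual gyrus	L	other
LING.R	Lingual gyrus	R	other
SOG.L	Superior occipital gyrus	L	other
SOG.R	Superior occipital gyrus	R	other
MOG.L	Middle occipital gyrus	L	other
MOG.R	Middle occipital gyrus	R	other
IOG.L	Inferior occipital gyrus	L	other
IOG.R	Inferior occipital gyrus	R	other
FFG.L	Fusiform gyrus	L	other
FFG.R	Fusiform gyrus	R	other
PoCG.L	Postcentral gyrus	L	other
PoCG.R	Postcentral gyrus	R	other
SPG.L	Superior parietal gyrus	L	other
SPG.R	Superior parietal gyrus	R	other
IPL.L	Inferior parietal lobule	L	CEN
IPL.R	Inferior parietal lobule	R	CEN
SMG.L	Supramarginal gyrus	L	other
SMG.R	Supramarginal gyrus	R	other
ANG.L	Angular gyrus	L	DMN
ANG.R	Angular gyrus	R	DMN
PCUN.L	Precuneus	L	DMN
PCUN.R	Precuneus	R	DMN
PCL.L	Paracentral lobule	L	other
PCL.R	Paracentral lobule	R	other
CAU.L	Caudate nucleus	L	other
CAU.R	Caudate nucleus	R	other
PUT.L	Lenticular nucleus, putamen	L	SN
PUT.R	Lenticular nucleus, putamen	R	SN
PAL.L	Lenticular nucleus, pallidum	L	SN
PAL.R	Lenticular nucleus, pallidum	R	SN
THA.L	Thalamus	L	other
THA.R	Thalamus	R	other
HES.L	Heschl gyrus	L	other
HES.R	Heschl gyrus	R	other
STG.L	Superior temporal gyrus	L	DMN
STG.R	Superior temporal gyrus	R	DMN
TPOsup.L	Temporal pole: superior temporal gyrus	L	other
TPOsup.R	Temporal pole: superior temporal gyrus	R	other
MTG.L	Middle temporal gyrus	L	DMN
MTG.R	Middle temporal gyrus	R	DMN
TPOmid.L	Temporal pole: middle temporal gyrus	L	other
TPOmid.R	Temporal pole: middle temporal gyrus	R	other
ITG.L	Inferior temporal gyrus	L	other
ITG.R	Inferior temporal gyrus	R	other
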