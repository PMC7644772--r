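name	lat	lon	species
Irogno Forest	-14.7491	48.4914	Mantidactylus ambreensis
Sahaovy, Makira Reserve	-15.4889	49.0785	Mantidactylus ambreensis
Camp Norbert, Manongarivo	-13.9481	48.4578	Mantidactylus ambreensis
Maromiandra near Ankaramy	-13.9965	48.2177	Mantidactylus ambreensis
Andampy Camp 0, Tsaratanana	-14.0422	48.7617	Mantidactylus ambreensis
Montagne d'Ambre	-12.4900	49.1719	Mantidactylus ambreensis
Foret d'Ambre	-12.4753	49.2142	Mantidactylus ambreensis
Bevintagnona Forest	-14.7385	48.5170	Mantidactylus ambreensis
Gite d'Etape, Montagne d'Ambre	-12.5280	49.1720	Mantidactylus ambony
Montagne d'Ambre mid-elevation	-12.5257	49.1729	Mantidactylus ambony
Montagne d'Ambre mid-elevation	-12.5209	49.1666	Mantidactylus ambony
Montagne d'Ambre western slope	-12.5910	49.1366	Mantidactylus ambony
Montagne d'Ambre ca. 1000 m	-12.5170	49.1670	Mantidactylus ambony
Lac Maudit, Montagne d'Ambre	-12.5884	49.1542	Mantidactylus ambony
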